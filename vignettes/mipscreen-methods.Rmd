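---
title: "Screening proteomes for microProtein candidates: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening proteomes for microProtein candidates: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The biological problem

MicroProteins are small proteins that carry a single protein–protein
interaction domain and regulate larger multidomain relatives
post-translationally: by heterodimerizing with the target through the shared
domain they sequester it into non-functional complexes, changing DNA binding,
co-factor recruitment or localization. Trans-microProteins arise by gene
duplication followed by evolutionary trimming, so a candidate betrays itself
through three sequence-level signatures: it is small, it is homologous to a
larger multidomain protein, and — like many regulatory proteins — it tends to
have a high predicted instability index. `mipscreen` turns these signatures
into a screening pipeline over an annotated proteome.

## The filter cascade

Given a proteome with UniProt-style protein-existence levels and InterPro
annotations, `mip_screen()` applies, in order:

1. **Existence filter.** Proteins with existence level 5 ("existence
   uncertain") are removed. Proteins without a recorded level are kept: the
   filter removes positive evidence of uncertainty, and absence of
   annotation must not exclude a protein from a poorly annotated genome.
2. **Size partition.** Proteins of at most `size_boundary` (default 150)
   residues are candidate microProteins (cmiPs); the rest are potential
   targets. 150 residues is small enough that a protein is unlikely to hold
   more than one domain.
3. **Candidate clustering.** All cmiPs are compared all-vs-all; hits at or
   above 30 bits link two candidates as homologs. A hit in either search
   direction links both: heuristic search is not perfectly symmetric, and a
   well-defined homolog group needs a symmetric relation. Candidates with no
   link are *single-copy*.
4. **Target discovery.** Single-copy candidates are searched directly
   against the targets. For a candidate with homologs, the group (seed plus
   homologs — the seed is included so the profile always represents the
   candidate itself) is aligned and the profile searched against the
   targets. Hits below 10 or above 120 bits are discarded — too-dissimilar
   hits are noise, too-similar hits are recent duplicates rather than
   trimmed descendants — and the 10 best hits are kept, ties broken by
   ascending target identifier.
5. **Domain-architecture filter.** Targets annotated with exactly one
   distinct InterPro entry of type *Domain* are removed from every hit
   list: a single-domain protein cannot both dimerize with the candidate
   and retain a second, regulated function. Entries of type Family, Repeat
   or Site are not counted — they describe lineage or short motifs, not
   structural domains. Targets with *no* Domain entry are kept by default:
   removing unannotated targets would empty a poorly annotated proteome.
   The strict two-or-more-domains reading is available via
   `pipeline_params(drop_unannotated = TRUE)`.
6. **Homolog cap.** Candidates with more than `max_homologs` (default 10)
   homologous candidates are excluded: large conserved families of small
   proteins (calmodulins, thioredoxins) satisfy every other criterion but
   are not regulators born of domain loss. Smaller proteomes may warrant a
   lower cap (8 works well for the reviewed Arabidopsis proteome).
7. **Length margin.** Target hits less than 40 residues longer than the
   candidate are removed: so small a difference leaves no room for a second
   domain.

All boundaries are closed exactly as stated: a 150-residue protein is a
candidate and a 151-residue protein a target; a 29.9-bit link is discarded
and a 30.0-bit link kept; hits at exactly 10 or 120 bits survive the window;
exactly 10 homologs are allowed and 11 are not; a margin of exactly 40
residues is sufficient. The filter order follows the screening method's
description, with the length margin applied last; each filter only ever
removes groups or hits, so stage counts are monotonically non-increasing.

## The composite confidence score

Every surviving (candidate, target) hit becomes a scored pair. With
*coverage* defined as candidate length divided by target length,

\[
\mathrm{score} \;=\; \mathrm{coverage}\;\times\;
\underbrace{\frac{10}{1+e^{-k\,(100\,\mathrm{coverage}\;-\;m)}}}_{\text{coverage weight}}
\;\times\;
\underbrace{\frac{1}{1+e^{-0.1\,(\mathrm{II}-70)}}}_{\text{instability factor}},
\qquad k = 0.1,\; m = 50 ,
\]

where II is the instability index of the *candidate* sequence (high
predicted instability is a microProtein characteristic, not a target one).
The coverage weight is parenthesized as \(-k(100c - m)\): this is the only
reading that places the sigmoid midpoint (weight 5) at coverage 0.5 and
spans the open range (0, 10); the alternative parse \(-100kc - m\) is
saturated near 10 for every coverage and would make the weight a no-op.
The printed form of the published formula carries a leading
\(1/\mathrm{bitscore}\) against a \(\mathrm{bitscore}\) factor; read
literally the two cancel, which is the package default
(`formula_variant = "literal"`). Because the first factor is typographically
ambiguous, the other defensible parse — multiplying the product by the
bitscore — is implemented as `formula_variant = "bitscore_weighted"` rather
than silently chosen. A consequence of the literal variant worth knowing:
within the bitscore window, ranking depends only on coverage and
instability, not on alignment strength.

Pairs are ranked by descending score (ties broken by candidate then target
identifier, so ranking is a total order and permutation-invariant),
percentiles are `ceiling(100 * rank / N)` — rank 1 of a few hundred pairs
renders as percentile 1 — and the top `ceiling(0.10 * N)` pairs are flagged
high-confidence. A candidate's reported rank is that of its best pair.

### Instability index

The instability index of Guruprasad, Reddy and Pandit (1990) is
\((10/L)\sum_i \mathrm{DIWV}(x_i, x_{i+1})\) over consecutive dipeptides,
with the published 20×20 dipeptide instability weight table embedded in the
package. Values above 40 conventionally predict in-vitro instability.
Dipeptides containing a non-canonical residue (X, B, Z, U — all present in
real UniProt proteomes) contribute weight 1.0, a neutral value inside the
table's typical range; the index is undefined for sequences with fewer than
two canonical residues. The implementation is tested to 1e-9 against values
frozen from an established protein-analysis reference implementation.

## Homology backends

The pipeline needs pairwise search, multiple alignment, and profile search.
Two backends provide them behind one contract:

* **internal** (default): a Smith–Waterman / Needleman–Wunsch affine-gap
  aligner (Gotoh recursion) compiled with Rcpp, scoring with BLOSUM50 and
  the conventional penalties for that matrix (gap open 10, extend 1; a gap
  of length *g* costs `open + g·extend`). Raw scores are converted to bits
  as `raw × λ / ln 2` with a fixed nominal λ = 0.232 for BLOSUM50. This
  conversion is deliberately simple and documented as an approximation: it
  reproduces the *magnitude* of probabilistic-search bitscores for true
  homologies but slightly inflates the scores of random local alignments,
  so the background of a large search flirts with the 30-bit gate more than
  a real profile search would. Multiple alignment is center-star
  progressive alignment around the longest member; profile search scores
  the database against the profile's column-majority consensus (ties broken
  alphabetically, all-gap columns dropped). Everything runs with zero
  external binaries and is exactly reproducible.
* **hmmer**: shells out to `phmmer` (gap open/extend probabilities 0.1/0.1,
  BLOSUM50 — the production parameterization; note these are probabilistic
  gap parameters, not DP penalties, which is why the internal backend's
  penalties are stated separately), `hmmbuild` and `hmmsearch`, and to
  `mafft` for the group alignment. Bitscores are the tools' full-sequence
  bitscores.

The internal aligner is verified against two independent oracles (an
exhaustive recursive enumeration of all alignments on very short pairs, and
a start-pair enumeration with an independent prefix recursion up to length
12) and cross-checked against `Biostrings::pairwiseAlignment` on random
pairs. Tie-breaking everywhere is descending bitscore, then ascending
identifier: "top 10 hits" is otherwise undefined under ties.

## Cross-species conservation and co-expression

`conserved_candidates()` searches each focal candidate against the *full*
protein sets of companion proteomes (the least restrictive reading of
"has a homolog in that species"; `restrict_conservation_to_small` limits
the search to the other species' small proteins). A species counts as
conserved when any hit reaches 30 bits — the candidate homology gate, the
only stated homology threshold, reused in the absence of a separate printed
value — and candidates conserved in at least `min_species` (default 3)
other species are retained, each associated with its highest-scoring target
via `best_pair()`.

`significant_pairs()` computes, per candidate–target pair, the Pearson
correlation of expression across tissues with the conventional two-sided
t-test (`stats::cor.test`; the t-form is the default of the statistical
environment the method was developed in). A pair is significant when
|r| > 0.7 **and** p < 0.01, both strict; positive and negative
co-regulation both count, which is the only self-consistent reading of a
two-sided threshold. No multiple-testing correction is applied, matching
the method's usage. Zero-variance profiles yield a flagged, non-significant
result rather than an error. Expression values are correlated as given;
`log2p1 = TRUE` correlates `log2(x + 1)` instead, since whether profiles
were log-transformed upstream is generally unknowable. At 10 tissues the
joint rule is equivalent to |r| > 0.765, so a null pair is flagged with
probability ≈ 1.3%; consumers of small pair sets should expect that
false-positive allowance, and the package's calibration is verified by a
10,000-pair type-I simulation (0.01 ± 0.003).

## The synthetic-proteome generator

`simulate_proteome()` plants ground truth so the whole pipeline is testable
offline:

* **Ancestors** (default 20) of 250–600 residues with 2–4 annotated Domain
  entries.
* **Planted candidates**: one per ancestor, a second copy for every third
  ancestor so the homolog-profile path is exercised. Each consists of a
  28–38-residue core copied from one ancestor domain with point mutations
  at `mutation_rate` (default 5%), flanked by freshly drawn padding, for a
  total length of 60–140 residues. The drift model is deliberate: a
  *full-length* 95%-identical duplicate scores far above the 120-bit
  "too similar" gate and would be — correctly — discarded by the pipeline,
  so a recoverable planted candidate must conserve only a short core, the
  way real trans-microProteins conserve the dimerization domain while the
  rest of the sequence drifts beyond recognition. The chosen core length
  puts the candidate–ancestor bitscore at roughly 60–105 bits, inside the
  target window with margin on both sides.
* **Instability bias**: padding positions are drawn 45% from an
  unstable-residue pool (S, P, R, E, Q, M, H, I, Y — residues with high
  average dipeptide instability weights) and then topped up by greedy,
  randomized single-residue swaps until the whole-sequence index reaches at
  least 75. Both knobs were chosen so that composition bias alone does not
  make unrelated paddings homologous at the 30-bit gate: the pool mixture
  keeps the expected BLOSUM50 score of unrelated pool sequences negative,
  and the top-up draws its candidate residues at random so no shared motif
  is inserted across candidates.
* **Decoys**, each class tripping exactly one filter: small proteins at
  existence level 5; >150-residue single-Domain proteins (removed wherever
  they appear as targets); one family of 12 near-identical small proteins
  (each member has 11 homologs, one over the cap); and — the bulk — 250
  small unrelated proteins drawn from a stabilizing pool (instability index
  well below 40). The large unrelated class is deliberate: real proteomes
  are dominated by nondescript small proteins whose weak 10–25-bit hits
  against large proteins form the low-scoring background of the ranking,
  and a "top 10%" statement is only meaningful against such a background.
  With these defaults a screen scores roughly 2,000 pairs in well under a
  minute, every planted candidate's best pair lands in the high-confidence
  top 10%, and all pathological decoys are excluded.

`simulate_orthologs()` draws conservation per ancestor *family* (sibling
candidates share their core, so homology search cannot tell them apart and
a per-candidate truth would be unverifiable) from a profile that plants
clearly conserved (3–4 species) and clearly non-conserved (0–1 species)
families. The exactly-at-the-boundary counting rule (2 of 4 is dropped;
29.9 bits does not count, 30.0 does) is a property of the counting logic,
not of sequence content, and is tested with injected bitscores instead —
with the internal bits conversion, random 100–150-residue queries against a
whole proteome occasionally graze the 30-bit gate, so a sequence-level
fixture cannot decide that boundary reliably. Companion proteomes and
expression matrices derive offset RNG substreams from the user seed so that
no two generators replay the same residue draws.

`simulate_expression()` draws, per pair, bivariate normal profiles with the
requested population correlation, then maps them affinely onto a
non-negative expression-like scale (affine maps leave Pearson r unchanged).

### What the generator does not emulate

No indel evolution, no phylogenetic structure among ancestors, no
composition heterogeneity along real domains, no correlated annotation
errors, and expression noise is Gaussian rather than count-distributed.
Passing the planted-recovery tests therefore demonstrates that the cascade,
scoring and ranking behave as specified under controlled truth — not that
the screen's precision on a real proteome matches the fixture's.

## Numerical and design choices

* All randomness flows from one integer seed per generator call; the
  caller's RNG state is restored on exit, and fixed seeds give
  byte-identical FASTA/TSV output (floats are written with 6 significant
  digits for the same reason).
* Result tables are sorted with radix order on (score, candidate, target),
  making every output a deterministic function of the input bytes.
* The screen is organised as one entry point returning a classed object
  (`mip_screen`) with `print`, `summary` and `plot` methods; the summary's
  row vocabulary (total, targets, small proteins, microProteins,
  single-copy, homologous) matches the field's reporting convention so runs
  on real proteomes are directly comparable to published count tables.
* Problem sizes used by the test-suite and the acceptance script — a
  320-protein study fixture, 4 companion proteomes, 10,000 null expression
  pairs, oracle alignments up to length 12 — were chosen as the smallest
  sizes at which each property is meaningfully exercised.

## Known limitations

* The internal bits conversion uses an ungapped nominal λ; gapped random
  alignments are scored a few bits higher than a calibrated search would,
  which is visible only near the 30-bit gate of whole-proteome scans.
* Cis-microProteins (isoform-derived) are out of scope: their detection
  needs transcript structure, not proteome homology.
* The literal score variant ignores bitscore within the target window by
  construction; users wanting alignment strength in the ranking should
  select the `bitscore_weighted` variant explicitly.
* UniProt-to-Ensembl identifier mapping for expression joins is left to a
  user-supplied two-column table.
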