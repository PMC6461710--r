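---
title: "Methods: twin-tagged metabarcoding from reads to accepted detections"
author: "twintag package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin-tagged metabarcoding from reads to accepted detections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twintag)
```

## The problem

Environmental and invertebrate-derived DNA (e/iDNA) metabarcoding infers
the presence of vertebrate species from trace DNA — here, the blood meals
of haematophagous leeches — by PCR-amplifying short mitochondrial markers
(a 93-bp 16S fragment, a 389-bp 12S fragment, a 302-bp CytB fragment,
optionally a 250-bp COI region), sequencing the amplicons, and assigning
reads to a taxonomy. Three failure modes dominate this kind of survey:
sample misassignment through tag jumping, erroneous reference taxonomies,
and false positive/negative detections from stochastic low-template PCR.
`twintag` implements one coherent defence against each: twin-tag
demultiplexing with jump filtering, systematic reference-database
curation, probabilistic taxonomic assignment with an explicit
unknown-taxon branch, and replicate-based acceptance criteria with
quantified error rates.

## Twin-tag demultiplexing

Each first-round PCR attaches the *same* 5-nt sample tag (Tag 1) to both
ends of the product; each second-round PCR attaches a plate tag (Tag 2),
again as a twin pair. Chimeric molecules formed during pooling or
sequencing carry *non-matching* tag pairs and are therefore detectable.
The bundled Tag 1 set has 25 printed tags (one reserved for controls)
with minimum pairwise Hamming distance 3; with 20 plate tags the scheme
distinguishes 24 × 20 = 480 samples per library preparation. The Tag 2
sequences of the original design are user-supplied; the package ships a
documented default of 20 synthetic 5-mers, generated once under a fixed
seed with the same distance-3 guarantee.

Demultiplexing resolves each observed tag by exact-then-one-mismatch
lookup in a precomputed neighbourhood index. Because the minimum distance
is 3 ≥ 2·1 + 1, the one-mismatch spheres around tags are disjoint and
every possible 5-mer resolves to at most one tag — a property the test
suite verifies exhaustively over all 1,024 5-mers. A read pair is a
*twin* when both mates resolve to the same label, a *jump* when both
resolve but differ, and *unassigned* otherwise. Only two-level twins
mapped by the sample sheet are emitted (tags clipped); everything else is
counted and diverted. Reads whose resolved tags have no sample-sheet
entry — including control-tag reads — are counted as unidentifiable at
the sample level.

Accounting tables express the Tag 2 jump rate relative to total reads and
the Tag 1 jump/unidentifiable rates relative to the Tag 2 twins, with
percentages rounded half away from zero to one decimal; totals rows sum
raw counts and recompute percentages from the sums. One quirk of the
published accounting this package bundles (`exampleRunCounts()`): the
totals-row Tag 1 jump percentage prints as 2.5 but recomputes to 2.4 from
the summed counts; all other printed percentages reproduce exactly, so
the recomputed value is reported.

## Read processing

Per sample, read pairs are merged across their best ungapped overlap
(minimum overlap 16, mismatch fraction ≤ 0.25 within the overlap; at
agreements the merged quality is the larger of the two, at mismatches the
higher-quality base is kept with quality |Q₁ − Q₂|, floored at 2). The
marker primers are then located (substitutions only, 12% error rate per
primer by default, IUPAC-aware) and removed; inserts shorter than
⌈0.9 × expected length⌉ are dropped, as are inserts whose expected error
Σ 10^(−Q/10) exceeds 1.0. The merge and quality parameters are package
defaults — the upstream protocol names the steps but not the settings —
and all are configurable. Libraries pass a step only with > 1,000 raw
pairs (merge gate) and > 500 merged pairs (trim gate); the gate operates
per library, with the threshold arguments exposed. Surviving inserts are
dereplicated by exact identity; singletons are discarded and copy numbers
are carried in `;size=N` headers.

## Reference-database curation

Raw reference sets (headers `Species_name_Accession`) pass seven steps:

1. **Label filtering** — non-binomial labels (single words, `sp.`/`cf.`/
   `aff.`, numerals) are discarded; trinomials are truncated to species.
2. **Supplementary merging** — extra local sequences are added with
   accession-level deduplication (network retrieval is out of scope; the
   interface is file-based).
3. **Two-stage amplicon extraction** — records containing both primer
   sites (≤ 2 mismatches per primer by default) are trimmed to the
   insert; the remainder are locally aligned against the primer-stage
   inserts and recovered when the alignment covers ≥ 90% of the expected
   length. If *no* record carries primers the input is judged already
   trimmed and length-conforming records pass through — this is what
   makes the whole pipeline idempotent on its own output.
4. **Ambiguity removal** — any record with a non-ACGT character.
5. **Taxonomy reconciliation** — labels are matched against a reference
   taxonomy; synonym-table hits are relabelled to the accepted name
   (originals kept as keys); unknown species whose genus exists are
   grafted under that genus; the rest are withheld as orphans for manual
   decision. User-supplied keep-lists and relabel-lists mirror the manual
   break points of curator-in-the-loop pipelines.
6. **Mislabel screening** — see below.
7. **Haplotype dereplication** — within species and marker, identical
   sequences collapse to the lexicographically smallest accession; sole
   representatives pass automatically; identical sequences in *different*
   species are both retained.

### Sequence identity

Identity between two sequences is the number of matching columns of the
best local alignment (match +1, mismatch −1, gap −2) divided by the
*longer sequence length*. Normalising by length rather than by alignment
columns is deliberate: a short perfect seed between two unrelated
sequences would otherwise score near 1, which would make every
eligibility threshold meaningless. Under this definition identical
sequences score 1, one mismatch in 100 scores 0.99, and unrelated 93-mers
score far below 0.6. For sets of equal-length sequences the implementation
uses the equivalent (and much faster) Hamming identity.

### Mislabel screening

The screen replaces an external phylogeny-based tool with two
complementary, fully testable rules operating on the pairwise identity
matrix:

* **Leave-one-out neighbour consensus.** Each record's k = 5 nearest
  neighbours with identity ≥ 0.9 vote at each rank from order down to
  species; a consensus supported by ≥ 80% of voters that contradicts the
  record's own taxon flags the record at that rank, with the consensus
  lineage suggested. Records with fewer than three eligible neighbours
  are left alone — a sequence far from every cluster (a genuinely novel
  species) must not inherit a neighbour consensus. The vote iterates to a
  fixed point: flagged records lose their vote and the remainder are
  re-screened, so co-mislabelled sequences cannot shield one another.
* **Minority-faction rule.** Sequences are grouped into single-linkage
  components at identity 0.9. A label whose records are split, with its
  *majority* in a different component, marks its local records as an
  embedded faction: they are flagged with the component's anchored lead
  label (the label with the largest share of its global records in the
  component). This supplies the evidence a phylogenetic screen reads off
  non-monophyly and handles clusters so contaminated that the local vote
  is inverted.

Flags report the most basal conflicting rank, so a within-genus swap
counts at species rank and a cross-order contamination at order rank.
The two-rule design emerged from validation against planted ground
truth: the neighbour consensus alone provably cannot flag two
same-wrong-label records that dominate a thinned cluster, a configuration
that a 5% mislabelling rate produces routinely.

## Probabilistic taxonomic assignment

Assignment walks a four-rank tree (order, family, genus, species) rooted
above the orders. At each parent the candidate set is its children *plus
one unknown branch* representing taxa absent from the reference database.
Each candidate c gets a predictor vector

x_c = (1, no-references indicator, best identity of the query to
references beneath c, margin of that identity over the best sibling),

and the posterior over the K candidates mixes a uniform mislabelling
component with a prior-weighted multinomial regression:

p(c) = ε/K + (1 − ε) · softmax_c(βᵀx_c + log π_c).

The functional form of the predictors is this package's realisation of a
four-coefficient-per-rank contract; it is isolated behind the
`nodePredictors()`/`seqSimilarity()` interface so an alternative scorer
or predictor map can be swapped in without touching fitting or traversal.
Note the shared intercept is not identifiable in a softmax over
candidates; it is carried for interface stability and stays at its prior
mode.

**Priors.** Species priors concentrate 90% of the mass uniformly on an
expected-species list (e.g., the mammals known from the study region) and
10% on all others; internal nodes inherit the summed mass of their
descendant species. The unknown branch receives the mean raw mass of its
real siblings before renormalisation — a neutral share chosen so that
uniform species priors induce a uniform prior over children + unknown.
For reference-identical species the prior is exactly what breaks the tie,
and such assignments surface as low-probability/high-similarity rows for
manual inspection.

**Training sets.** 5,000 queries are drawn from the reference set: 4,500
known species — half with conspecific references retained, half with them
masked (species missing from the database) — and 500 novel lineages
distributed evenly across the four ranks by masking the corresponding
node and every reference beneath it, so the truth at the masked rank is
the unknown branch. All draws are reproducible under a seed.

**Fitting.** Each rank's five parameters (β, ε) are estimated by maximum
a posteriori with independent Gaussian(0, 10²) priors on β and a
Beta(1, 10) prior on ε, using deterministic quasi-Newton ascent (L-BFGS-B
with analytic gradients) from the fixed start β = 0, ε = 0.01 —
a gradient method with far better conditioning than plain gradient
ascent, and bit-reproducible given the fixed start. Degenerate designs in
which every case has a single candidate leave ε unidentifiable and
return the start value with a warning.

**Calibration by simulation.** The recovery study simulates candidate
sets with *independent* predictor variation and samples outcomes from the
model at known (β\*, ε\*). Independence matters: predictors harvested
from a real tree are strongly collinear (the margin is a function of the
similarities), and the Fisher information of that geometry puts the
parameter standard errors near 1 at n = 5,000, which no estimator can
beat. With an informative design the fit recovers β within ±0.3 and ε
within ±0.05 at n = 5,000 across seeds, as the acceptance suite checks.
Moderate true effects (β\* = (0, −1, 3, 1.5), ε\* = 0.1) are used because
saturating effects flatten the likelihood and push any estimator toward
its prior.

**Classification** descends greedily from the root, multiplying the
winning candidate's posterior into a cumulative placement probability;
once the unknown branch wins, deeper ranks report "unknown" at the
cumulative probability reached. Each assignment carries the best
reference similarity of the assigned species (or genus when the species
is unknown) so that high-probability/low-similarity and
low-probability/high-similarity conflicts can be flagged for review.

## Replicate-based detection acceptance

Each sample × species combination is observed over 12 PCR reactions: 2
extraction replicates (A/B) × 2 cycle variants (30/40 cycles) × 3
markers. A cell is *positive* at ≥ 1 assigned read by default (the
replicate-level threshold is not fixed by the protocol; the read-count
rule below carries the read-depth evidence). Libraries that were never
sequenced are *absent*, not zero, and drop out of denominators. Two
criteria are evaluated side by side:

* **lax** — any ≥ 2 positive cells of the 12;
* **stringent** — ≥ 1 positive A-cell *and* ≥ 1 positive B-cell.

Both are conjoined with the read-count rule: a single-marker detection
needs ≥ 10 reads summed over that marker's cells, while a multi-marker
detection stands even when individual markers fall below 10.

With per-PCR detection probability p and the full 6 + 6 design,

* stringent acceptance = (1 − (1 − p)⁶)²,
* lax acceptance = 1 − (1 − p)¹² − 12p(1 − p)¹¹,

both verified against exhaustive enumeration over all 2¹² outcome
patterns. Since a stringent acceptance is also a lax acceptance for every
one of the 4,096 positivity patterns, the stringent criterion has a
higher false-negative rate and a lower false-positive rate at every p —
the quantitative trade-off the two criteria exist to expose. A Monte
Carlo simulator reproduces the closed forms within binomial error and
extends them to designs with missing cells.

The bundled per-species detection counts (`exampleDetections()`) sum to a
change column of +28 between criteria; their printed column totals
(162/190) are one lower than the per-species sums (163/191), an internal
inconsistency of the source table that the package documents and does not
reproduce — `speciesSummary()` always reports computed sums.

## The synthetic-data generator

`fixtureSpec()` fixes the simulation conditions: a balanced taxonomy
(default 3 orders × 2 families × 2 genera × 3 species = 36 species),
8 accessions per species over 3 haplotypes (GenBank-style redundancy),
intra-species haplotypes exactly round(0.005 × L) substitutions from the
species base sequence, species diverged from a genus ancestor at rate 0.2
per site (pairwise inter-species divergence ≈ 30%, comfortably above the
10% the curation tests assume), constant Q35 qualities, substitution-only
sequencing errors, Dirichlet-multinomial species mixes per sample, and
independently planted anomalies (subspecies labels, ambiguity codes,
synonyms, cluster-inconsistent mislabels, short fragments, graftable
novel species, orphan labels) whose positions are recorded in a manifest
sufficient to compute every expected downstream output.

What the generator does *not* emulate: indel sequencing errors, chimera
formation beyond tag jumps, quality decay along reads, amplification bias
between species, and the deep unevenness of real reference databases.
Passing tests therefore demonstrate correctness of the algorithms under
controlled conditions, not field performance on degraded iDNA.

## Problem sizes and numerical choices

The test and acceptance runs use 10⁵ read pairs for the demultiplexing
round trip, a 291-record reference database for curation recovery, all
4,096 replicate patterns for the criterion oracles, 10⁵ Monte-Carlo
replicates for error-rate agreement, and n = 5,000 simulated cases for
parameter recovery — sizes at which every stochastic check operates at
least three standard errors from its pass boundary. Posterior sums are
asserted to 10⁻⁹; the optimizer's convergence contract is a gradient norm
below 10⁻⁶ or 10,000 iterations. Ties are broken deterministically
throughout (lexicographic sequence order in dereplication, smallest
accession in haplotype collapse, first-listed marker in primer
identification).

## Known limitations

* The mislabel screen assumes intra-species clusters are tighter than
  0.9 identity and species clusters are separated below it; markers with
  genuinely overlapping species (deep 16S conservation) will route
  shared-haplotype species to the keep-list workflow rather than an
  automated decision.
* The predictor map is a stand-in realisation of a four-coefficient
  contract; swapping in another published parameterisation only requires
  a new `nodePredictors()`.
* Closed-form error rates assume the full 6 + 6 design; samples with
  absent libraries are screened on their available cells, but their
  error rates are not re-derived in closed form (the Monte-Carlo path
  covers them).
* The merge-quality model caps merged qualities at the difference of the
  mate qualities at mismatches, a conservative convention; downstream
  expected-error filtering treats those bases accordingly.
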