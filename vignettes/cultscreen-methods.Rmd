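---
title: "Methods: scoring a culturable plant-microbiota screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring a culturable plant-microbiota screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cultscreen)
```

# The screen

`cultscreen` implements the computational layer of a culturable
plant-microbiota screen of the kind run on aromatic medicinal plants such as
oregano (*Origanum vulgare* L.). Bacteria are isolated from four
compartments — flower, leaf, stem and bulk soil (codes F, L, S, T; strain ids
follow the `OV` + code + number convention) — and then characterized by four
assays whose arithmetic this package reproduces:

1. **RAPD haplotyping.** Isolates are fingerprinted by arbitrary-primer PCR;
   isolates with identical band patterns are treated as one strain
   (haplotype).
2. **Censored antibiograms.** Each strain is streaked on plates carrying an
   ascending antibiotic concentration ladder and its growth graded on a
   five-level ordinal scale; the minimal inhibitory concentration (MIC) is
   read off the ladder, possibly censored at either end.
3. **Cross-streak antagonism.** Every strain is tested as tester and as
   target; inhibition is scored 0–3 and aggregated per tester (total score of
   inhibition, TSI) and per compartment.
4. **Essential-oil chemotyping.** The host oil's GC–MS composition is
   summarized into compound-class totals and a chemotype label; retention
   positions are expressed as linear retention indices (LRI) against an
   n-alkane series.

# Models and procedures

## Haplotype dereplication

`dereplicate()` groups isolates if and only if their 0/1 band vectors are
*exactly* identical. Band matching uses no similarity threshold: the assay
compares presence/absence of bands, and published screens of this design
report haplotypes as identical fingerprints. Since vector identity is an
equivalence relation, grouping by pattern equals the transitive closure of
pairwise equality; the test suite asserts this against a brute-force
all-pairs oracle on random instances up to 50 isolates × 20 bins. For users
starting from raw band sizes, `build_band_bins()` constructs a shared bin
schema by single-linkage merging of sizes closer than a configurable
tolerance (default 0, i.e. exact sizes).

One isolate per haplotype is chosen as representative strain, uniformly at
random and deterministically per seed (`choose_representative()`); the seed
is recorded in pipeline manifests so runs are reproducible.

## Compartment sharing

`venn_partition()` assigns each taxon (or haplotype) to exactly the subset
of compartments where it occurs. Pairwise shared counts are *total*
intersections: a taxon present in three compartments contributes to all
three pairs. Shared percentages follow the reporting precision conventional
in these screens: nearest integer for taxonomic ranks, one decimal for
haplotypes.

A deliberate caveat: in the packaged 62-strain panel the leaf–soil and
stem–soil shared-genus cells of the original summary table cannot be derived
from the strain table under either a total or an exclusive counting rule
(the strain table shares Arthrobacter and Bacillus, plus Staphylococcus for
stem–soil). `cultscreen` reports the set-theoretic counts and documents the
discrepancy rather than reproducing those two cells.

## Censored MIC calling

`determine_mic()` scans a strain's ordinal growth grades along the ladder.
"Growth" means a grade at or above the `growth_cutoff`; the default cutoff
is `very_weak`, i.e. only complete absence of growth counts as inhibited,
reflecting how tolerant environmental isolates are usually read. The MIC is
the lowest rung above the highest rung showing growth. Growth at the top
rung right-censors the MIC (`>top`); no growth anywhere left-censors it
(`<bottom`). A non-monotone series (growth reappearing above an inhibited
rung, e.g. a skipped well) is called conservatively above the highest
growing rung and flagged `non_monotone`.

Threshold summaries (`threshold_fraction()`) use censored semantics: a
left-censored MIC satisfies any `at_or_below` threshold at or above the
bottom rung, a right-censored MIC satisfies `at_or_above` thresholds up to
the top rung. Two conventions are worth making explicit because they are
what the printed percentages of such screens actually use:

* summaries phrased as "MIC below c" are computed *inclusively*
  (`at_or_below c`) — that is the rule under which the packaged panel
  reproduces every printed percentage (e.g. 28/62 strains at streptomycin
  ≤ 2.5 µg/ml = 45.16%);
* percentages are *truncated*, not rounded, to two decimals
  (23/62 = 37.0967 → 37.09).

`at_or_above` at the top rung counts both exact top-rung calls and
right-censored calls ("at the maximum concentration used or more").

## Antagonism scoring

`tsi()` sums a tester's 0–3 scores over its scored targets; not-determined
(`Nd`) cells and never-assayed pairs are both treated as missing and
excluded, but carry distinct provenance flags in the matrix. The activity
bins — absence (0), very low (1–10), low (11–20), strong (21–27), very
strong (28–30) — presuppose a 10-target panel; for other panel sizes
`tsi_category()` scales the bin edges proportionally to the maximum
attainable score (`n`, `2n`, `2.7n`, `3n` for `n` scored targets), which
reduces exactly to the raw bins at `n = 10`.

`compartment_scores()` aggregates a full matrix by compartment: inhibitory
sums over cross-compartment cells with the tester in the focal compartment,
sensitivity sums symmetrically for targets, and within-compartment cells
reported separately as self-inhibition (an `include_self` flag folds them
into the directed sums, since published score tables do not always state
their construction). The inhibition potential divides the inhibitory sum by
the number of tester strains; `pct_max` columns normalize by the maximum
attainable score (3 per scored cell). Missing cells never contribute, so
the directed plus self sums conserve the matrix total exactly — a property
the tests assert on random matrices.

Published compartment-level score tables of this design print non-integer
values whose normalization is not stated; such tables are therefore shipped
as a ranking fixture (`compartment_antagonism_scores.tsv`) consumed by
`rank_compartments()`, not recomputed. Ranking breaks ties alphabetically
and flags them.

## Chemotyping

`lri()` uses the van den Dool–Kratz linear interpolation
`100 (n + (t − t_n)/(t_{n+1} − t_n))`; it is exact on every alkane point,
strictly increasing, and refuses extrapolation outside the series.
`class_totals()` sums relative abundances over the five compound classes and
derives terpene-hydrocarbon and oxygenated totals; mass is conserved.
`chemotype_label()` names the oil after its `k` (default 2) most abundant
constituents joined with `/`; a tie at the k-th rank reports all tied
compounds alphabetically and sets a tie flag, because their order is
arbitrary.

The packaged oil composition (`eo_composition_synthetic.csv`) is
*synthetic*: full compositions live in supplementary tables that are not
redistributed, so the file pins the constituents and aggregate properties a
germacrene D/β-caryophyllene chemotype exhibits (leading abundances 29.4%
and 19.2%, sesquiterpene hydrocarbons above 70%, terpene hydrocarbons above
90%, oxygenated terpenes 8.6%) and fills the remainder with plausible minor
constituents.

# The synthetic-data generators

`sim_config()` fixes the study conditions; its defaults mirror the screen's
scale: four compartments with (16, 17, 19, 12) strains dereplicated from
(24, 24, 25, 24) isolates, a 19-genus pool with a sharing rate of 0.37
(≈ 7/19 genera in two or more compartments), two haplotypes shared between
leaf and stem, 20 band-size bins, and the six packaged antibiotic ladders.

Design choices that matter:

* **Seed fan-out.** One global seed derives independent per-generator
  sub-streams, so adding or rerunning one generator never perturbs
  another's output; all generators are bit-reproducible per seed.
* **Genus pools.** Each genus is shared (assigned to a uniformly drawn
  subset of ≥ 2 compartments) with probability `genus_sharing_rate`, else
  private. When strain capacity allows, every pool genus is observed at
  least once, so pool-level sharing is realized in the observed table
  (sharing rate 0 forces zero observed sharing; rate 1 over two
  compartments shares everything).
* **Planted MICs.** Each strain × antibiotic cell draws a true MIC with
  configurable mass on left censoring, exact rungs and right censoring
  (default 0.3/0.5/0.2). Exact MICs are never planted on the lowest rung:
  such a cell yields an all-`none` series indistinguishable from left
  censoring, so it is unidentifiable by construction. Grade noise flips one
  random rung's reading with probability `grade_noise_p` per cell; at 5%
  noise the calling recovers ≥ 90% of planted MICs over ~500 cells, at zero
  noise 100%.
* **Inhibition probabilities.** Cross-compartment cells inhibit with the
  tester compartment's `p_cross`, within-compartment cells with `p_within`
  (default 0.2). A scalar cross probability carries no ordering, so
  `p_cross` is per-compartment; the default gradient soil 0.8 > stem 0.65 >
  leaf 0.5 > flower 0.35 (mean ≈ 0.6) emulates the inhibitory gradient such
  screens observe while keeping cross inhibition well above within
  inhibition. The planted inhibitory ordering (descending `p_cross`) is
  recovered by `rank_compartments()` in at least 18 of 20 seeds at 15
  strains per compartment; at the default gap of 0.15 between adjacent
  compartments recovery is essentially certain.

What the generators do *not* emulate: gel-band size jitter and band-calling
error (profiles are exact), phylogenetic structure within genera, antibiotic
cross-resistance correlations between drugs, medium- and
temperature-dependence of inhibition, and any sequence-level signal. Passing
tests on synthetic data therefore certify the arithmetic and the recovery
properties of the estimators under the declared noise model, not robustness
to those unmodelled features of real plate data.

# Numerical choices and degenerate inputs

* Percentages: truncation to 2 decimals for antibiogram summaries; rounding
  to integer (taxa) or 1 decimal (haplotypes) for sharing; these mirror the
  printed conventions the fixtures are checked against.
* MIC text dialect: `"<0.5"`, `"2.5"`, `">50"`; `"5.0"` equals `"5"`;
  parser and formatter are exact inverses over every packaged ladder.
* Empty inputs: an empty strain table is valid (richness 0); an empty
  antibiogram yields a warned zero fraction; an empty composition has zero
  class totals but no chemotype label.
* Ties: compartment ranking and chemotype labelling break ties
  alphabetically and flag them rather than picking silently.
* Strain-id/compartment mismatches under the `OV` convention are errors,
  not warnings, to catch transcription slips in fixtures; genus spelling
  variants are unified through an explicit versioned map and unmapped names
  pass through unchanged.

# Problem sizes

The test suite and the acceptance script run everything at the screen's own
scale: 62-strain panels, ≤ 50 × 20 dereplication instances against the
brute-force oracle, ~500-cell MIC-recovery simulations, and 20-seed
ordering sweeps at 60 strains — a few seconds each on one CPU, which is the
scale at which these assays are actually run and read.

# Known limitations

* Species-level sharing is exercised on synthetic data only; strain tables
  without species annotations simply exclude those records (with a count).
* The two internally inconsistent pairwise cells of the published genus
  summary (leaf–soil, stem–soil) are documented, not reproduced.
* Compartment-level published score tables are ranked, not rederived; their
  normalization is unknown.
* The TSI bin scaling for non-10-target panels is a proportional extension
  of the published scheme, not itself a published rule.
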