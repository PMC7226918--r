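# cultscreen

Analysis of culturable plant-microbiota screens: the arithmetic that turns
plate readings from a four-compartment screen (flower, leaf, stem, bulk
soil) of a medicinal plant such as oregano into the numbers such studies
report.

For microbiologists running culturomics screens, the package covers:

* **RAPD haplotyping** — `dereplicate()` collapses isolates with identical
  presence/absence band profiles into haplotypes, `choose_representative()`
  picks seeded random representatives, `haplotype_summary()` counts
  distribution and sharing across compartments.
* **Compartment sharing** — `richness()`, `pairwise_shared()`,
  `venn_partition()` and `sharing_summary()` partition genera (or species,
  or haplotypes) by the exact compartment subset they occupy.
* **Censored antibiograms** — `determine_mic()` calls the minimal
  inhibitory concentration (MIC) from ordinal growth grades over an
  antibiotic concentration ladder, with left/right censoring (`<0.5`,
  `>50`); `threshold_fraction()` computes censoring-aware threshold
  summaries; `resistance_table()` formats the panel.
* **Cross-streak antagonism** — `tsi()` computes the total score of
  inhibition (sum of 0–3 scores, binned absence / very low 1–10 / low
  11–20 / strong 21–27 / very strong 28–30 on a 10-target panel),
  `compartment_scores()` aggregates inhibitory, sensitivity and
  self-inhibition sums with the inhibition potential (sum / n testers),
  `pathogen_panel_summary()` stratifies by pathogen group and Gram class.
* **Essential-oil chemotyping** — `lri()` (van den Dool–Kratz linear
  retention index against an n-alkane series), `class_totals()` and
  `chemotype_label()`.
* **Synthetic data** — seeded generators (`sim_config()`, `gen_strains()`,
  `gen_band_profiles()`, `gen_growth_grades()`, `gen_interaction_matrix()`,
  `simulate_bundle()`) emulating the screen's design with planted truth, so
  every stage is testable without external data.
* **Pipeline** — `run_pipeline()` wires any subset of stages from a YAML or
  list config and writes TSV/JSON reports plus a reproducible manifest.

A transcribed 62-strain antibiogram panel of an oregano screen, the
matching compartment antagonism score table, a 46-strain human-pathogen
panel, and a synthetic essential-oil composition ship under
`inst/extdata/`.

## Worked example

```r
library(cultscreen)

panel <- read_antibiogram(system.file("extdata", "oregano_strain_mic.tsv",
                                      package = "cultscreen"))
r <- threshold_fraction(panel, "streptomycin", "at_or_below", 2.5)
sprintf("streptomycin <=2.5: %d/%d = %.2f%%", r$count, r$total, r$percent)
#> streptomycin <=2.5: 28/62 = 45.16%

strains <- panel$strains
richness(strains, "genus")
#> 19
attr(venn_partition(strains, "genus"), "shared_any")
#> 7

comp <- read_eo_composition(system.file("extdata",
                                        "eo_composition_synthetic.csv",
                                        package = "cultscreen"))
chemotype_label(comp)
#> germacrene D/beta-caryophyllene
class_totals(comp)$oxygenated
#> 8.6
```

Reading: 28 of the 62 strains have an MIC at or below 2.5 µg/ml
streptomycin (left-censored `<0.5` calls included) — 45.16% of the panel.
The 62 strains span 19 genera, 7 of which occur in two or more
compartments. The packaged (synthetic) oil is a germacrene
D/β-caryophyllene chemotype with 8.6% oxygenated terpenes.

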