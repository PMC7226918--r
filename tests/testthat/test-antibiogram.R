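test_that("MIC calling follows the censored scan rule", {
  ladder <- antibiotic_ladders()$streptomycin
  all_none <- determine_mic(rep("-", 6), ladder)
  expect_equal(all_none$mic, 0.5)
  expect_equal(all_none$censor, "below_lowest")

  all_growth <- determine_mic(rep("++", 6), ladder)
  expect_equal(all_growth$mic, 50)
  expect_equal(all_growth$censor, "above_highest")

  # growth at 0.5 and 1, none from 2.5 on -> MIC 2.5 exact
  scan <- determine_mic(c("++", "+", "-", "-", "-", "-"), ladder)
  expect_equal(scan$mic, 2.5)
  expect_equal(scan$censor, "exact")
  expect_equal(scan$flag, "")
})

test_that("growth cutoff is configurable and very-weak growth counts by default", {
  ladder <- antibiotic_ladders()$streptomycin
  vw <- c("++", "+", "+--", "-", "-", "-")
  expect_equal(determine_mic(vw, ladder)$mic, 5)
  expect_equal(determine_mic(vw, ladder, growth_cutoff = "weak")$mic, 2.5)
})

test_that("non-monotone series are called conservatively and flagged", {
  ladder <- antibiotic_ladders()$streptomycin
  # inhibited at 1, growth back at 5: MIC above the highest growth rung
  odd <- determine_mic(c("++", "-", "-", "+", "-", "-"), ladder)
  expect_equal(odd$mic, 10)
  expect_equal(odd$flag, "non_monotone")
})

test_that("ladder-mismatched growth series are rejected", {
  ladder <- antibiotic_ladders()$rifampicin
  expect_error(determine_mic(rep("-", 3), ladder), "one reading per ladder rung")
  df <- data.frame(concentration = c(5, 10, 25, 50, 99), grade = "-")
  expect_error(determine_mic(df, ladder), "exactly once")
})

test_that("the packaged antibiogram reproduces every printed summary", {
  panel <- published_panel()
  str_low <- threshold_fraction(panel, "streptomycin", "at_or_below", 2.5)
  expect_equal(str_low$count, 28)
  expect_equal(str_low$percent, 45.16)

  str_high <- threshold_fraction(panel, "streptomycin", "at_or_above", 50)
  expect_equal(str_high$count, 23)
  expect_equal(str_high$percent, 37.09)

  kan_high <- threshold_fraction(panel, "kanamycin", "at_or_above", 50)
  expect_equal(kan_high$count, 26)
  expect_equal(kan_high$percent, 41.93)

  tet_low <- threshold_fraction(panel, "tetracycline", "at_or_below", 2.5)
  expect_equal(tet_low$count, 52)
  expect_equal(tet_low$percent, 83.87)

  rif_tolerant <- threshold_fraction(panel, "rifampicin", "above", 5)
  expect_equal(rif_tolerant$count, 12)
})

test_that("threshold counting honours censored semantics and rejects off-ladder thresholds", {
  panel <- published_panel()
  # left-censored cells satisfy at_or_below at the lowest rung
  low <- threshold_fraction(panel, "streptomycin", "at_or_below", 0.5)
  expect_equal(low$count, 17)
  # at_or_below counts are non-decreasing in the threshold
  ladder <- antibiotic_ladders()$streptomycin
  counts <- vapply(ladder, function(conc) {
    threshold_fraction(panel, "streptomycin", "at_or_below", conc)$count
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
  # at_or_below max and strictly-above max partition the panel
  above <- threshold_fraction(panel, "streptomycin", "above", max(ladder))
  expect_equal(counts[length(counts)] + above$count, 62)
  expect_error(threshold_fraction(panel, "streptomycin", "at_or_below", 100),
               "outside")
  expect_error(threshold_fraction(panel, "penicillin", "at_or_below", 1),
               "not in panel")
})

test_that("an empty panel yields a warned zero fraction", {
  empty <- cultscreen:::new_antibiogram(
    tibble::tibble(strain_id = character(), antibiotic = character(),
                   mic = numeric(), censor = character(), flag = character()),
    antibiotic_ladders()
  )
  expect_warning(res <- threshold_fraction(empty, "streptomycin",
                                           "at_or_below", 2.5),
                 "Empty panel")
  expect_equal(res$count, 0L)
  expect_equal(res$percent, 0)
})

test_that("the resistance table is compartment-sorted and round-trips", {
  panel <- published_panel()
  tab <- resistance_table(panel)
  expect_equal(nrow(tab), 62)
  expect_equal(sum(names(tab) %in% names(antibiotic_ladders())), 6)
  # sorted in canonical compartment order: flower, leaf, stem, soil
  expect_false(is.unsorted(as.integer(tab$compartment)))
  expect_equal(tab$streptomycin[tab$strain_id == "OVT1"], ">50")

  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(tab, path, progress = FALSE)
  back <- read_antibiogram(path)
  merged <- dplyr::inner_join(panel$calls, back$calls,
                              by = c("strain_id", "antibiotic"))
  expect_equal(nrow(merged), nrow(panel$calls))
  expect_equal(merged$mic.x, merged$mic.y)
  expect_equal(merged$censor.x, merged$censor.y)
})

test_that("MIC calling recovers planted values: perfectly at zero noise, >= 90% at 5% grade noise", {
  cfg0 <- sim_config(seed = 21, grade_noise_p = 0)
  strains <- gen_strains(cfg0)
  sim0 <- gen_growth_grades(cfg0, strains)
  called0 <- call_mics(sim0$grades)$calls
  merged0 <- dplyr::inner_join(called0, sim0$truth,
                               by = c("strain_id", "antibiotic"))
  expect_equal(nrow(merged0), nrow(sim0$truth))
  expect_true(all(merged0$mic.x == merged0$mic.y &
                  merged0$censor.x == merged0$censor.y))

  # ~500 cells: 84 strains x 6 antibiotics under noise
  cfg1 <- sim_config(seed = 11, grade_noise_p = 0.05,
                     strains_per_compartment = c(flower = 21, leaf = 21,
                                                 stem = 21, soil = 21),
                     isolates_per_compartment = c(flower = 21, leaf = 21,
                                                  stem = 21, soil = 21))
  strains1 <- gen_strains(cfg1)
  sim1 <- gen_growth_grades(cfg1, strains1)
  expect_gte(nrow(sim1$truth), 500)
  called1 <- call_mics(sim1$grades)$calls
  merged1 <- dplyr::inner_join(called1, sim1$truth,
                               by = c("strain_id", "antibiotic"))
  recovery <- mean(merged1$mic.x == merged1$mic.y &
                   merged1$censor.x == merged1$censor.y)
  expect_gte(recovery, 0.90)
})
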