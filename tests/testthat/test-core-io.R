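test_that("the packaged strain table reads into 62 records with the expected compartment counts", {
  strains <- published_strains()
  expect_equal(nrow(strains), 62)
  expect_equal(as.vector(table(strains$compartment)), c(16, 15, 19, 12))
  expect_true(all(nzchar(strains$genus)))
  # spelling variants are unified
  expect_true("Rathayibacter" %in% strains$genus)
  expect_false("Rathaybacter" %in% strains$genus)
})

test_that("strain table parsing rejects malformed inputs and accepts the empty table", {
  base <- tibble::tibble(strain_id = paste0("OVF", 1:5),
                         compartment = "flower", genus = "Bacillus")
  dup <- base; dup$strain_id[4] <- "OVF2"
  expect_error(read_strain_table(write_tsv_fixture(dup)), "OVF2")

  badcomp <- base; badcomp$compartment[3] <- "root"
  expect_error(read_strain_table(write_tsv_fixture(badcomp)), "row")

  mismatch <- base; mismatch$compartment[2] <- "soil"
  expect_error(read_strain_table(write_tsv_fixture(mismatch)), "OVF2")

  empty <- read_strain_table(write_tsv_fixture(base[0, ]))
  expect_equal(nrow(empty), 0)
})

test_that("genus normalization strips markup, fixes case, and maps known variants", {
  expect_equal(normalize_genus(c("*Bacillus*", "  pseudomonas ", "Sphyngomonas",
                                 "Rathaybacter", "Novelgenus")),
               c("Bacillus", "Pseudomonas", "Sphingomonas",
                 "Rathayibacter", "Novelgenus"))
})

test_that("MIC formatting matches the printed dialect", {
  expect_equal(format_mic(0.5, "below_lowest"), "<0.5")
  expect_equal(format_mic(50, "above_highest"), ">50")
  expect_equal(format_mic(2.5, "exact"), "2.5")
})

test_that("parse/format round-trips every censored MIC over every packaged ladder", {
  for (ab in names(antibiotic_ladders())) {
    ladder <- antibiotic_ladders()[[ab]]
    mics <- tibble::tibble(
      mic = c(min(ladder), ladder, max(ladder)),
      censor = c("below_lowest", rep("exact", length(ladder)), "above_highest")
    )
    reparsed <- parse_mic(format_mic(mics$mic, mics$censor), ladder)
    expect_equal(reparsed$mic, mics$mic)
    expect_equal(reparsed$censor, mics$censor)
  }
  # whitespace and trailing-zero variants parse to the same value
  expect_equal(parse_mic("< 0.5"), parse_mic("<0.5"))
  expect_equal(parse_mic("5.0")$mic, parse_mic("5")$mic)
})

test_that("MIC values inconsistent with their ladder are rejected", {
  ladder <- antibiotic_ladders()$streptomycin
  expect_error(parse_mic("3", ladder), "inconsistent")
  expect_error(parse_mic("<1", ladder), "inconsistent")
  expect_error(parse_mic(">10", ladder), "inconsistent")
})

test_that("interaction tables load with Nd distinguished from absent pairs", {
  df <- data.frame(tester = c("t1", "t1", "t2", "t2"),
                   target = c("g1", "g2", "g1", "g2"),
                   score = c(0, 1, 2, 3))
  m <- interaction_matrix(df)
  expect_equal(dim(interaction_scores(m)), c(2, 2))
  expect_false(anyNA(interaction_scores(m)))

  nd <- data.frame(tester = c("t1", "t1"), target = c("g1", "g2"),
                   score = c("Nd", "2"))
  mnd <- read_interaction_table(write_tsv_fixture(nd))
  expect_true(is.na(interaction_scores(mnd)["t1", "g1"]))
  expect_equal(mnd$provenance["t1", "g1"], "nd")

  # a pair never assayed is also missing, but with distinct provenance
  sparse <- interaction_matrix(data.frame(tester = "t1", target = "g1", score = 1),
                               testers = c("t1", "t2"), targets = c("g1", "g2"))
  expect_true(is.na(interaction_scores(sparse)["t2", "g2"]))
  expect_equal(sparse$provenance["t2", "g2"], "absent")

  bad <- data.frame(tester = "t1", target = "g1", score = 5)
  expect_error(interaction_matrix(bad), "row")
})

test_that("interaction tables round-trip through write/read", {
  case <- random_interaction_case(7)
  path <- tempfile(fileext = ".tsv")
  write_interaction_table(case$matrix, path)
  back <- read_interaction_table(path)
  expect_equal(interaction_scores(back)[rownames(case$matrix$scores),
                                        colnames(case$matrix$scores)],
               interaction_scores(case$matrix))
})

test_that("marker FASTA sequences attach to strains by id", {
  skip_if_not_installed("Biostrings")
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">OVF1", "ACGTACGT", ">OVF2", "GGGCCC"), fa)
  strains <- tibble::tibble(strain_id = c("OVF1", "OVF2"),
                            compartment = "flower", genus = "Bacillus")
  seqs <- read_marker_fasta(fa, strains)
  expect_equal(seqs$strain_id, c("OVF1", "OVF2"))
  writeLines(c(">OVX9", "ACGT"), fa)
  expect_error(read_marker_fasta(fa, strains), "OVX9")
})
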