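test_that("TSI sums a tester's scores and bins into activity categories", {
  df <- expand.grid(tester = c("t1", "t2", "t3"), target = paste0("g", 1:10),
                    stringsAsFactors = FALSE)
  scores <- c(t1 = 3, t2 = 0, t3 = NA)
  df$score <- ifelse(df$tester == "t1", 3, 0)
  hand <- c(3, 2, 1, 3, 2, 1, 2, 1, 0, 0)
  df$score[df$tester == "t3"] <- hand[match(df$target[df$tester == "t3"],
                                            paste0("g", 1:10))]
  m <- interaction_matrix(df)
  res <- tsi(m)
  expect_equal(res$tsi[res$tester_id == "t1"], 30)
  expect_equal(res$category[res$tester_id == "t1"], "very_strong")
  expect_equal(res$tsi[res$tester_id == "t2"], 0)
  expect_equal(res$category[res$tester_id == "t2"], "absence")
  expect_equal(res$tsi[res$tester_id == "t3"], 15)
  expect_equal(res$category[res$tester_id == "t3"], "low")
  expect_error(tsi(m, "t9"), "not in matrix")
})

test_that("TSI categories partition 0-30 exactly as the published bins", {
  expected <- c("absence",
                rep("very_low", 10),   # 1-10
                rep("low", 10),        # 11-20
                rep("strong", 7),      # 21-27
                rep("very_strong", 3)) # 28-30
  expect_equal(tsi_category(0:30, n_scored = 10), expected)
  expect_error(tsi_category(31, n_scored = 10), "3 x n_scored")
  # scaled bins reduce to the same scheme and cover other panel sizes
  expect_equal(tsi_category(0:15 * 2, n_scored = 10),
               expected[0:15 * 2 + 1])
  expect_equal(tsi_category(c(0, 5, 10, 13, 15), n_scored = 5),
               c("absence", "very_low", "low", "strong", "very_strong"))
})

test_that("TSI is permutation-invariant over targets and unaffected by Nd cells", {
  case <- random_interaction_case(3)
  m <- case$matrix
  perm <- m
  ord <- sample(ncol(m$scores))
  perm$scores <- m$scores[, ord]
  perm$provenance <- m$provenance[, ord]
  expect_equal(tsi(perm)$tsi, tsi(m)$tsi)
  # adding Nd rows to the long table changes no sums
  long <- case$long
  extra <- data.frame(tester = long$tester[1], target = "ghost", score = "Nd")
  m2 <- interaction_matrix(rbind(long, extra))
  expect_equal(tsi(m2)$tsi, tsi(m)$tsi)
})

test_that("compartment aggregation matches the hand-computed toy example", {
  toy <- toy_compartment_matrix()
  cs <- compartment_scores(toy$matrix, toy$strains)
  a <- cs[cs$compartment == "flower", ]
  b <- cs[cs$compartment == "soil", ]
  expect_equal(a$inhibitory_sum, 6)
  expect_equal(a$self_inhibition_sum, 2)
  expect_equal(a$sensitivity_sum, 2)
  expect_equal(b$inhibitory_sum, 2)
  expect_equal(b$self_inhibition_sum, 0)
  expect_equal(b$sensitivity_sum, 6)
  expect_equal(a$inhibition_potential, 6 / 2)
  # single tester scoring 3 against 4 foreign targets
  df <- data.frame(tester = "a1", target = paste0("b", 1:4), score = 3)
  strains <- tibble::tibble(strain_id = c("a1", paste0("b", 1:4)),
                            compartment = c("flower", rep("soil", 4)),
                            genus = "G")
  cs1 <- compartment_scores(interaction_matrix(df), strains)
  expect_equal(cs1$inhibitory_sum[cs1$compartment == "flower"], 12)
  expect_equal(cs1$inhibition_potential[cs1$compartment == "flower"], 12)
  expect_equal(cs1$sensitivity_sum[cs1$compartment == "soil"], 12)
  # all-zero matrix
  df0 <- df; df0$score <- 0
  cs0 <- compartment_scores(interaction_matrix(df0), strains)
  expect_true(all(cs0$inhibitory_sum == 0 & cs0$sensitivity_sum == 0 &
                  cs0$self_inhibition_sum == 0))
  expect_error(compartment_scores(toy$matrix, toy$strains[1:2, ]),
               "without compartment")
})

test_that("compartment sums conserve the matrix total and ignore missing cells", {
  for (seed in 1:8) {
    case <- random_interaction_case(seed)
    cs <- compartment_scores(case$matrix, case$strains)
    total_cells <- sum(case$matrix$scores, na.rm = TRUE)
    expect_equal(sum(cs$inhibitory_sum) + sum(cs$self_inhibition_sum),
                 total_cells)
    expect_equal(sum(cs$sensitivity_sum) + sum(cs$self_inhibition_sum),
                 total_cells)
    # inclusive mode folds self cells into both directed sums
    inc <- compartment_scores(case$matrix, case$strains, include_self = TRUE)
    expect_equal(sum(inc$inhibitory_sum), total_cells)
  }
})

test_that("compartment ranking reproduces the published score ordering", {
  scores <- readr::read_tsv(fixture_path("compartment_antagonism_scores.tsv"),
                            show_col_types = FALSE)
  inh <- rank_compartments(scores, "inhibitory_score")
  expect_equal(inh, c("soil", "stem", "leaf", "flower"), ignore_attr = TRUE)
  expect_false(attr(inh, "ties"))
  sens <- rank_compartments(scores, "sensitivity_score", decreasing = FALSE)
  expect_equal(sens, c("soil", "flower", "stem", "leaf"), ignore_attr = TRUE)
  tied <- tibble::tibble(compartment = c("stem", "leaf"), v = c(1, 1))
  r <- rank_compartments(tied, "v")
  expect_equal(r, c("leaf", "stem"), ignore_attr = TRUE)
  expect_true(attr(r, "ties"))
})

test_that("pathogen panel summaries count inhibition per group and Gram class", {
  df <- expand.grid(tester = c("t1", "t2"),
                    target = c("gp1", "gp2", "gn1", "gn2"),
                    stringsAsFactors = FALSE)
  df$score <- 0
  df$score[df$tester == "t1" & df$target == "gp1"] <- 3
  df$score[df$tester == "t1" & df$target == "gp2"] <- 2
  df$score[df$tester == "t2" & df$target == "gp1"] <- 1
  meta <- tibble::tibble(target_id = c("gp1", "gp2", "gn1", "gn2"),
                         group = c("S_aureus", "S_aureus", "BCC", "BCC"),
                         gram = c("positive", "positive", "negative", "negative"))
  res <- pathogen_panel_summary(interaction_matrix(df), meta)
  pg <- res$per_gram
  expect_equal(pg$pct_inhibited[pg$gram == "positive"], 75)
  expect_equal(pg$pct_inhibited[pg$gram == "negative"], 0)
  expect_equal(res$active_testers$n_active, 2)
  expect_equal(res$active_testers$fraction, 1)
  pt <- res$per_tester
  expect_equal(pt$tsi[pt$tester_id == "t1" & pt$group == "S_aureus"], 5)
  expect_equal(pt$pct_inhibited[pt$tester_id == "t1" & pt$group == "S_aureus"], 100)
  # threshold 2 restricts to strong-or-complete inhibition
  strong <- pathogen_panel_summary(interaction_matrix(df), meta, threshold = 2)
  expect_equal(strong$active_testers$n_active, 1)
  expect_error(pathogen_panel_summary(interaction_matrix(df), meta[1:3, ]),
               "Unannotated")
})

test_that("a tester inhibiting 9 of 10 targets scores 90 percent", {
  df <- data.frame(tester = "t1", target = paste0("sa", 1:10),
                   score = c(rep(2, 9), 0))
  meta <- tibble::tibble(target_id = paste0("sa", 1:10), group = "S_aureus",
                         gram = "positive")
  res <- pathogen_panel_summary(interaction_matrix(df), meta)
  expect_equal(res$per_tester$pct_inhibited, 90)
})

test_that("an all-zero pathogen panel reports no active testers", {
  df <- expand.grid(tester = c("t1", "t2"), target = c("p1", "p2"),
                    stringsAsFactors = FALSE)
  df$score <- 0
  meta <- tibble::tibble(target_id = c("p1", "p2"), group = "BCC",
                         gram = "negative")
  res <- pathogen_panel_summary(interaction_matrix(df), meta)
  expect_true(all(res$per_gram$pct_inhibited == 0))
  expect_equal(res$active_testers$n_active, 0)
})
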