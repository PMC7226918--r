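#' Total score of inhibition (TSI) per tester
#'
#' The TSI of a tester strain is the sum of its ordinal inhibition scores
#' (0-3) over a target panel; missing cells are excluded from the sum and
#' counted separately. Against a 10-target panel the TSI is binned into
#' activity categories: absence (0), very low (1-10), low (11-20), strong
#' (21-27), very strong (28-30). For other panel sizes the same bin edges are
#' scaled proportionally to the maximum attainable score `3 x n_scored`
#' (edges `n`, `2n`, `2.7n`, `3n`), which reduces exactly to the raw bins
#' when `n_scored = 10`.
#'
#' @param matrix An [interaction_matrix()].
#' @param tester_id Tester id(s); default all testers.
#' @return Tibble: `tester_id`, `n_targets_scored`, `n_missing`, `tsi`,
#'   `category`.
#' @export
tsi <- function(matrix, tester_id = NULL) {
  stopifnot(inherits(matrix, "interaction_matrix"))
  tester_id <- tester_id %||% rownames(matrix$scores)
  missing <- setdiff(tester_id, rownames(matrix$scores))
  if (length(missing) > 0) {
    abort(paste0("Tester(s) not in matrix: ", paste(missing, collapse = ", ")))
  }
  rows <- matrix$scores[tester_id, , drop = FALSE]
  tibble(
    tester_id = tester_id,
    n_targets_scored = unname(apply(rows, 1, function(r) sum(!is.na(r)))),
    n_missing = unname(apply(rows, 1, function(r) sum(is.na(r)))),
    tsi = unname(apply(rows, 1, function(r) sum(r, na.rm = TRUE)))
  ) |>
    mutate(category = tsi_category(.data$tsi, .data$n_targets_scored))
}

#' @rdname tsi
#' @param score TSI value(s).
#' @param n_scored Number of scored targets (default 10, the reference panel
#'   size of the binning scheme).
#' @export
tsi_category <- function(score, n_scored = 10) {
  if (length(n_scored) == 1) n_scored <- rep(n_scored, length(score))
  if (any(score < 0 | score > 3 * n_scored)) {
    abort("TSI must lie in [0, 3 x n_scored]")
  }
  dplyr::case_when(
    score == 0 ~ "absence",
    score <= 1.0 * n_scored ~ "very_low",
    score <= 2.0 * n_scored ~ "low",
    score <= 2.7 * n_scored ~ "strong",
    TRUE ~ "very_strong"
  )
}

#' Compartment-level antagonism scores
#'
#' Aggregates an interaction matrix by the compartment of origin of testers
#' and targets. For each compartment: `inhibitory_sum` totals scores of its
#' testers against targets from *other* compartments; `sensitivity_sum`
#' totals scores received by its targets from testers of other compartments;
#' `self_inhibition_sum` totals within-compartment cells. Set
#' `include_self = TRUE` to fold self cells into both directed sums. The
#' inhibition potential is `inhibitory_sum / n_testers`; `pct_max` columns
#' normalize each sum by its maximum attainable value (3 per scored cell).
#' Missing (nd/absent) cells are excluded everywhere.
#'
#' @param matrix An [interaction_matrix()].
#' @param strains Strain table resolving every tester/target to a compartment.
#' @param include_self Include within-compartment cells in the directed sums
#'   (default `FALSE`; they are always reported as `self_inhibition_sum`).
#' @return Tibble with one row per compartment present.
#' @export
compartment_scores <- function(matrix, strains, include_self = FALSE) {
  stopifnot(inherits(matrix, "interaction_matrix"))
  comp <- setNames(as.character(strains$compartment), strains$strain_id)
  ids <- union(rownames(matrix$scores), colnames(matrix$scores))
  unresolved <- setdiff(ids, names(comp))
  if (length(unresolved) > 0) {
    abort(paste0("Strain(s) without compartment: ",
                 paste(unresolved, collapse = ", ")))
  }
  long <- tidyr::expand_grid(tester = rownames(matrix$scores),
                             target = colnames(matrix$scores)) |>
    mutate(score = matrix$scores[cbind(.data$tester, .data$target)]) |>
    filter(!is.na(.data$score)) |>
    mutate(tc = comp[.data$tester], gc = comp[.data$target],
           self = .data$tc == .data$gc)
  comps <- sort(unique(c(long$tc, long$gc, comp[rownames(matrix$scores)])))
  comps <- factor(comps, levels = names(.compartment_codes))
  comps <- as.character(sort(comps))
  out <- purrr::map_dfr(comps, function(cc) {
    inh_cells <- long[long$tc == cc & (!long$self | include_self), ]
    sen_cells <- long[long$gc == cc & (!long$self | include_self), ]
    self_cells <- long[long$tc == cc & long$self, ]
    n_testers <- sum(comp[rownames(matrix$scores)] == cc)
    tibble(
      compartment = cc,
      n_testers = n_testers,
      inhibitory_sum = sum(inh_cells$score),
      sensitivity_sum = sum(sen_cells$score),
      self_inhibition_sum = sum(self_cells$score),
      inhibition_potential = ifelse(n_testers > 0,
                                    sum(inh_cells$score) / n_testers, NA_real_),
      inhibitory_pct_max = pct_of_max(inh_cells$score),
      sensitivity_pct_max = pct_of_max(sen_cells$score)
    )
  })
  out$compartment <- factor(out$compartment, levels = names(.compartment_codes))
  out
}

pct_of_max <- function(scores) {
  if (length(scores) == 0) return(NA_real_)
  sum(scores) / (3 * length(scores)) * 100
}

#' Rank compartments by an antagonism attribute
#'
#' @param scores Tibble with a `compartment` column and numeric attributes,
#'   e.g. from [compartment_scores()] or a published score table.
#' @param by Attribute column to rank by.
#' @param decreasing Rank descending (default) or ascending.
#' @return Character vector of compartment labels in rank order; attribute
#'   `ties` flags whether any scores were equal (ties broken alphabetically).
#' @examples
#' scores <- tibble::tibble(compartment = c("soil", "stem", "leaf", "flower"),
#'                          inhibitory_score = c(63.41, 47.62, 44.21, 32.27))
#' rank_compartments(scores, "inhibitory_score")
#' @export
rank_compartments <- function(scores, by, decreasing = TRUE) {
  if (nrow(scores) == 0) abort("No compartment scores to rank")
  if (!by %in% names(scores)) abort(paste0("No such attribute: ", by))
  v <- scores[[by]]
  lab <- as.character(scores$compartment)
  ord <- order(if (decreasing) -v else v, lab)
  out <- lab[ord]
  attr(out, "ties") <- anyDuplicated(v) > 0
  out
}

#' Pathogen-panel antagonism summary
#'
#' Summarizes a tester x pathogen interaction matrix per tester, per pathogen
#' group and per Gram class. "Inhibited" means a score at or above
#' `threshold` (default 1; use 2 for "strong or complete").
#'
#' @param matrix An [interaction_matrix()] whose targets are pathogens.
#' @param pathogens Tibble annotating every target: columns `target_id`,
#'   `group` (e.g. S. aureus, CoNS, P. aeruginosa, K. pneumoniae, BCC) and
#'   `gram` (`"positive"`/`"negative"`).
#' @param threshold Minimum score counted as inhibition.
#' @return List with tibbles `per_tester` (`tester_id`, `group`, `tsi`,
#'   `n_scored`, `n_inhibited`, `pct_inhibited`), `per_gram` (`gram`,
#'   `n_scored`, `n_inhibited`, `pct_inhibited`) and `active_testers`
#'   (`n_active`, `n_testers`, `fraction`): testers inhibiting at least one
#'   pathogen.
#' @export
pathogen_panel_summary <- function(matrix, pathogens, threshold = 1) {
  stopifnot(inherits(matrix, "interaction_matrix"))
  needed <- c("target_id", "group", "gram")
  if (!all(needed %in% names(pathogens))) {
    abort(paste0("pathogens needs columns: ", paste(needed, collapse = ", ")))
  }
  unannotated <- setdiff(colnames(matrix$scores), pathogens$target_id)
  if (length(unannotated) > 0) {
    abort(paste0("Unannotated target(s): ", paste(unannotated, collapse = ", ")))
  }
  meta <- pathogens[match(colnames(matrix$scores), pathogens$target_id), ]
  long <- tidyr::expand_grid(tester_id = rownames(matrix$scores),
                             target_id = colnames(matrix$scores)) |>
    mutate(score = matrix$scores[cbind(.data$tester_id, .data$target_id)]) |>
    left_join(meta, by = "target_id") |>
    filter(!is.na(.data$score))
  per_tester <- long |>
    group_by(.data$tester_id, .data$group) |>
    summarise(tsi = sum(.data$score), n_scored = dplyr::n(),
              n_inhibited = sum(.data$score >= threshold),
              pct_inhibited = mean(.data$score >= threshold) * 100,
              .groups = "drop")
  per_gram <- long |>
    group_by(.data$gram) |>
    summarise(n_scored = dplyr::n(),
              n_inhibited = sum(.data$score >= threshold),
              pct_inhibited = mean(.data$score >= threshold) * 100,
              .groups = "drop")
  active <- long |>
    group_by(.data$tester_id) |>
    summarise(active = any(.data$score >= threshold), .groups = "drop")
  n_testers <- nrow(matrix$scores)
  list(
    per_tester = per_tester,
    per_gram = per_gram,
    active_testers = tibble(n_active = sum(active$active),
                            n_testers = n_testers,
                            fraction = sum(active$active) / n_testers)
  )
}
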