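#' Cross-streak interaction matrices
#'
#' An interaction matrix holds ordinal inhibition scores (0 = absence,
#' 1 = weak, 2 = strong, 3 = complete) of tester strains against target
#' strains. Missing cells are `NA` and carry a provenance flag: `"nd"` for
#' assays whose result was not obtained, `"absent"` for pairs never listed.
#' All aggregations exclude both kinds of missing cell identically.
#'
#' @param df Long data frame with columns `tester`, `target`, `score`
#'   (integers 0-3, or `"Nd"`/`NA` for not determined).
#' @param testers,targets Optional orderings; default: order of appearance.
#' @return An `interaction_matrix`: list with integer matrix `scores`
#'   (testers x targets, `NA` = missing) and character matrix `provenance`
#'   (`"scored"`, `"nd"`, `"absent"`).
#' @examples
#' m <- interaction_matrix(data.frame(tester = c("a", "a"), target = c("x", "y"),
#'                                    score = c(3, "Nd")))
#' interaction_scores(m)
#' @export
interaction_matrix <- function(df, testers = NULL, targets = NULL) {
  needed <- c("tester", "target", "score")
  if (!all(needed %in% names(df))) {
    abort(paste0("Interaction table needs columns: ", paste(needed, collapse = ", ")))
  }
  raw <- trimws(as.character(df$score))
  is_nd <- is.na(raw) | tolower(raw) == "nd"
  score <- suppressWarnings(as.numeric(raw))
  bad <- which(!is_nd & (is.na(score) | !score %in% 0:3))
  if (length(bad) > 0) {
    abort(paste0("Score outside {0,1,2,3,Nd} in row(s): ",
                 paste(bad, collapse = ", "),
                 " (", paste(unique(raw[bad]), collapse = ", "), ")"))
  }
  testers <- testers %||% unique(as.character(df$tester))
  targets <- targets %||% unique(as.character(df$target))
  key <- paste(df$tester, df$target, sep = "\r")
  if (anyDuplicated(key)) {
    abort(paste0("Duplicate tester/target pair(s): ",
                 paste(unique(gsub("\r", " vs ", key[duplicated(key)])), collapse = ", ")))
  }
  scores <- matrix(NA_integer_, length(testers), length(targets),
                   dimnames = list(testers, targets))
  provenance <- matrix("absent", length(testers), length(targets),
                       dimnames = list(testers, targets))
  idx <- cbind(match(as.character(df$tester), testers),
               match(as.character(df$target), targets))
  scores[idx] <- ifelse(is_nd, NA_integer_, as.integer(score))
  provenance[idx] <- ifelse(is_nd, "nd", "scored")
  structure(list(scores = scores, provenance = provenance),
            class = "interaction_matrix")
}

#' @rdname interaction_matrix
#' @param x An `interaction_matrix`.
#' @export
interaction_scores <- function(x) {
  stopifnot(inherits(x, "interaction_matrix"))
  x$scores
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat("<interaction_matrix> ", nrow(x$scores), " testers x ", ncol(x$scores),
      " targets (", sum(x$provenance == "scored"), " scored, ",
      sum(x$provenance == "nd"), " nd)\n", sep = "")
  invisible(x)
}

#' Read a long-format interaction table
#'
#' @param path Path to a table with columns `tester`, `target`, `score`
#'   (0-3 or `Nd`).
#' @param dialect `"tsv"` or `"csv"`.
#' @return An [interaction_matrix()].
#' @export
read_interaction_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  df <- read_table_dialect(path, dialect)
  names(df) <- tolower(names(df))
  interaction_matrix(df)
}

#' Write an interaction matrix back to long format
#'
#' Only scored and nd cells are written; absent pairs are omitted, so the
#' table round-trips through [read_interaction_table()].
#'
#' @param x An `interaction_matrix`.
#' @param path Output path (TSV).
#' @export
write_interaction_table <- function(x, path) {
  stopifnot(inherits(x, "interaction_matrix"))
  long <- tidyr::expand_grid(tester = rownames(x$scores),
                             target = colnames(x$scores)) |>
    mutate(
      prov = x$provenance[cbind(.data$tester, .data$target)],
      score = ifelse(.data$prov == "nd", "Nd",
                     as.character(x$scores[cbind(.data$tester, .data$target)]))
    ) |>
    filter(.data$prov != "absent") |>
    select("tester", "target", "score")
  readr::write_tsv(long, path, progress = FALSE)
  invisible(path)
}
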