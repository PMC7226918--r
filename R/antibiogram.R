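#' Ordinal growth grades
#'
#' Growth on an antibiotic-supplemented plate is scored on a five-level
#' ordinal scale: complete (`++`) > strong (`+`) > weak (`+-`) > very weak
#' (`+--`) > none (`-`). The printed symbols for weak and very weak are
#' visually identical in some published tables; the scale keeps them distinct
#' internally and this package uses `+-` vs `+--` in text files.
#'
#' @return Character vector of grade levels, lowest first.
#' @export
growth_grade_levels <- function() {
  c("none", "very_weak", "weak", "strong", "complete")
}

.grade_symbols <- c("++" = "complete", "+" = "strong", "+-" = "weak",
                    "+--" = "very_weak", "-" = "none")

# Accept either symbols or level names; returns level names.
parse_grade <- function(x) {
  x <- trimws(as.character(x))
  out <- ifelse(x %in% names(.grade_symbols), .grade_symbols[x], tolower(x))
  bad <- setdiff(out, growth_grade_levels())
  if (length(bad) > 0) {
    abort(paste0("Unknown growth grade(s): ", paste(unique(bad), collapse = ", ")))
  }
  unname(out)
}

grade_rank <- function(grade) match(grade, growth_grade_levels()) - 1L

#' Call a censored MIC from a growth series
#'
#' The MIC is the lowest tested concentration at which growth is inhibited
#' and stays inhibited at all higher rungs. "Growth" means a grade at or above
#' `growth_cutoff` (default `"very_weak"`: only full absence of growth counts
#' as inhibited). If growth persists at the highest rung the MIC is right
#' censored (`> highest`); if growth is already absent at the lowest rung it
#' is left censored (`< lowest`). A non-monotone series (growth reappearing
#' above an inhibited rung) is called conservatively as the lowest rung above
#' the highest rung showing growth, and flagged `non_monotone`.
#'
#' @param grades Growth grades, one per ladder rung: either a character vector
#'   aligned with `ladder`, or a two-column data frame with `concentration`
#'   and `grade`.
#' @param ladder Ascending concentration ladder (ug/ml).
#' @param growth_cutoff Least grade still counted as growth.
#' @return One-row tibble: `mic`, `censor`, `flag` (`""` or `"non_monotone"`).
#' @examples
#' determine_mic(c("++", "+", "-", "-", "-", "-"), antibiotic_ladders()$streptomycin)
#' @export
determine_mic <- function(grades, ladder, growth_cutoff = "very_weak") {
  validate_ladder(ladder)
  if (is.data.frame(grades)) {
    if (!all(c("concentration", "grade") %in% names(grades))) {
      abort("grades data frame needs columns concentration and grade")
    }
    conc <- as.numeric(grades$concentration)
    if (length(conc) != length(ladder) || anyDuplicated(conc) ||
        !setequal(conc, ladder)) {
      abort("grades must cover each ladder rung exactly once")
    }
    grades <- grades$grade[order(conc)]
  }
  if (length(grades) != length(ladder)) {
    abort("grades must have one reading per ladder rung")
  }
  grade <- parse_grade(grades)
  cutoff_rank <- grade_rank(parse_grade(growth_cutoff))
  if (cutoff_rank < 1) abort("growth_cutoff must be above 'none'")
  growth <- grade_rank(grade) >= cutoff_rank
  if (!any(growth)) {
    return(tibble(mic = min(ladder), censor = "below_lowest", flag = ""))
  }
  h <- max(which(growth))
  flag <- if (any(!growth[seq_len(h - 1)])) "non_monotone" else ""
  if (h == length(ladder)) {
    return(tibble(mic = max(ladder), censor = "above_highest", flag = flag))
  }
  tibble(mic = ladder[h + 1], censor = "exact", flag = flag)
}

#' Build an antibiogram panel from long growth grades
#'
#' Applies [determine_mic()] to every strain x antibiotic series of a long
#' growth-grade table.
#'
#' @param grade_table Long tibble with columns `strain_id`, `antibiotic`,
#'   `concentration`, `grade` (symbols or level names).
#' @param ladders Named list of ladders; every antibiotic in the table must be
#'   named.
#' @param growth_cutoff Passed to [determine_mic()].
#' @param strains Optional strain table attached for reporting.
#' @return An `antibiogram` object: list with `calls` (tibble `strain_id`,
#'   `antibiotic`, `mic`, `censor`, `flag`), `ladders`, `strains`.
#' @export
call_mics <- function(grade_table, ladders = antibiotic_ladders(),
                      growth_cutoff = "very_weak", strains = NULL) {
  needed <- c("strain_id", "antibiotic", "concentration", "grade")
  if (!all(needed %in% names(grade_table))) {
    abort(paste0("grade table needs columns: ", paste(needed, collapse = ", ")))
  }
  unknown <- setdiff(unique(grade_table$antibiotic), names(ladders))
  if (length(unknown) > 0) {
    abort(paste0("No ladder declared for antibiotic(s): ",
                 paste(unknown, collapse = ", ")))
  }
  calls <- grade_table |>
    mutate(concentration = as.numeric(.data$concentration)) |>
    group_by(.data$strain_id, .data$antibiotic) |>
    dplyr::group_modify(function(d, key) {
      determine_mic(d[, c("concentration", "grade")],
                    ladders[[key$antibiotic]], growth_cutoff)
    }) |>
    ungroup()
  new_antibiogram(calls, ladders, strains)
}

new_antibiogram <- function(calls, ladders, strains = NULL) {
  for (ab in unique(calls$antibiotic)) {
    check_mic_ladder(calls[calls$antibiotic == ab, c("mic", "censor")],
                     ladders[[ab]])
  }
  structure(list(calls = as_tibble(calls), ladders = ladders, strains = strains),
            class = "antibiogram")
}

#' @export
print.antibiogram <- function(x, ...) {
  cat("<antibiogram> ", dplyr::n_distinct(x$calls$strain_id), " strains x ",
      dplyr::n_distinct(x$calls$antibiotic), " antibiotics\n", sep = "")
  print(head(x$calls, 10))
  invisible(x)
}

#' Read a pre-called MIC table
#'
#' Reads a wide resistance table (one row per strain; one column per
#' antibiotic holding MIC cells in the `"<0.5"` / `"2.5"` / `">50"` dialect)
#' together with the strain metadata columns understood by
#' [read_strain_table()].
#'
#' @param path Path to the table.
#' @param ladders Named list of concentration ladders; columns matching a
#'   ladder name are parsed as MIC columns.
#' @param dialect `"tsv"` or `"csv"`.
#' @return An `antibiogram` object (see [call_mics()]).
#' @export
read_antibiogram <- function(path, ladders = antibiotic_ladders(),
                             dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  df <- read_table_dialect(path, dialect)
  names(df) <- tolower(names(df))
  ab_cols <- intersect(names(ladders), names(df))
  if (length(ab_cols) == 0) abort("No antibiotic columns found")
  strains <- read_strain_table_df(df[setdiff(names(df), ab_cols)])
  long <- df[c("strain_id", ab_cols)] |>
    tidyr::pivot_longer(dplyr::all_of(ab_cols), names_to = "antibiotic",
                        values_to = "cell")
  calls <- dplyr::bind_cols(
    long[c("strain_id", "antibiotic")],
    parse_mic(long$cell)
  )
  calls$flag <- ""
  for (ab in ab_cols) {
    check_mic_ladder(calls[calls$antibiotic == ab, c("mic", "censor")],
                     ladders[[ab]])
  }
  new_antibiogram(calls, ladders[ab_cols], strains)
}

# Validate an in-memory strain data frame with the same rules as
# read_strain_table().
read_strain_table_df <- function(df) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  readr::write_tsv(df, tmp, progress = FALSE)
  read_strain_table(tmp)
}

#' Censoring-aware threshold summaries of an antibiogram
#'
#' Counts strains whose MIC satisfies a threshold predicate under censored
#' semantics: a left-censored MIC (`< lowest`) satisfies `at_or_below c` for
#' any `c >=` lowest rung; a right-censored MIC (`> highest`) satisfies
#' `at_or_above c` for any `c <=` highest rung and `above c` for any
#' `c <` infinity within the ladder. `at_or_above` at the highest rung counts
#' both exact top-rung calls and right-censored calls ("at the maximum
#' concentration used or more").
#'
#' The percentage is truncated (not rounded) to `digits` decimals, the
#' convention of the printed summaries.
#'
#' @param panel An `antibiogram`.
#' @param antibiotic Antibiotic name present in the panel.
#' @param predicate `"at_or_below"`, `"at_or_above"`, or `"above"` (strictly).
#' @param conc Threshold concentration; must lie within the ladder range.
#' @param digits Decimals kept in the percentage (default 2).
#' @return List: `count`, `total`, `fraction`, `percent`.
#' @examples
#' \dontrun{
#' panel <- read_antibiogram(system.file("extdata", "oregano_strain_mic.tsv",
#'                                       package = "cultscreen"))
#' threshold_fraction(panel, "streptomycin", "at_or_below", 2.5)$percent  # 45.16
#' }
#' @export
threshold_fraction <- function(panel, antibiotic,
                               predicate = c("at_or_below", "at_or_above", "above"),
                               conc, digits = 2) {
  predicate <- match.arg(predicate)
  stopifnot(inherits(panel, "antibiogram"))
  if (nrow(panel$calls) == 0) {
    warn("Empty panel: fraction defined as 0")
    return(list(count = 0L, total = 0L, fraction = 0, percent = 0))
  }
  if (!antibiotic %in% panel$calls$antibiotic) {
    abort(paste0("Antibiotic not in panel: ", antibiotic))
  }
  ladder <- panel$ladders[[antibiotic]]
  if (conc < min(ladder) || conc > max(ladder)) {
    abort(paste0("Threshold ", conc, " outside the ", antibiotic,
                 " ladder range [", min(ladder), ", ", max(ladder), "]"))
  }
  cells <- panel$calls[panel$calls$antibiotic == antibiotic, ]
  total <- nrow(cells)
  if (total == 0) {
    warn("Empty panel: fraction defined as 0")
    return(list(count = 0L, total = 0L, fraction = 0, percent = 0))
  }
  hit <- switch(predicate,
    at_or_below = (cells$censor == "below_lowest") |
      (cells$censor == "exact" & cells$mic <= conc),
    at_or_above = (cells$censor == "above_highest") |
      (cells$censor == "exact" & cells$mic >= conc),
    above = (cells$censor == "above_highest") |
      (cells$censor == "exact" & cells$mic > conc)
  )
  count <- sum(hit)
  list(count = as.integer(count), total = as.integer(total),
       fraction = count / total,
       percent = truncate_pct(count / total, digits))
}

#' Format an antibiogram as a resistance table
#'
#' One row per strain, MIC cells in the text dialect of [format_mic()],
#' sorted by compartment (flower, leaf, stem, soil) then strain id. The
#' result round-trips through [read_antibiogram()].
#'
#' @param panel An `antibiogram` with attached strain metadata.
#' @return Wide tibble: strain metadata columns then one column per antibiotic.
#' @export
resistance_table <- function(panel) {
  stopifnot(inherits(panel, "antibiogram"))
  wide <- panel$calls |>
    mutate(cell = format_mic(.data$mic, .data$censor)) |>
    select("strain_id", "antibiotic", "cell") |>
    tidyr::pivot_wider(names_from = "antibiotic", values_from = "cell")
  if (!is.null(panel$strains)) {
    wide <- dplyr::left_join(panel$strains, wide, by = "strain_id") |>
      arrange(.data$compartment, .data$strain_id)
  }
  wide
}
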