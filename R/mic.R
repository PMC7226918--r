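#' Antibiotic concentration ladders
#'
#' The concentration series (in ug/ml) over which each antibiotic was tested
#' in the screen. Each ladder is a strictly ascending numeric vector; MIC
#' values are always reported relative to one of these ladders, with left
#' censoring below the lowest rung and right censoring above the highest.
#'
#' @return Named list of numeric vectors (ug/ml).
#' @examples
#' antibiotic_ladders()$streptomycin
#' @export
antibiotic_ladders <- function() {
  list(
    chloramphenicol = c(1, 2.5, 5, 10, 25, 50),
    ciprofloxacin   = c(0.5, 1, 2.5, 5, 10, 50),
    streptomycin    = c(0.5, 1, 2.5, 5, 10, 50),
    kanamycin       = c(0.5, 1, 2.5, 5, 10, 50),
    rifampicin      = c(5, 10, 25, 50, 100),
    tetracycline    = c(0.5, 1.25, 2.5, 5, 12.5, 25)
  )
}

validate_ladder <- function(ladder) {
  if (!is.numeric(ladder) || length(ladder) < 2 || any(ladder <= 0) ||
      any(diff(ladder) <= 0)) {
    abort("A concentration ladder must be >= 2 strictly ascending positive values")
  }
  invisible(ladder)
}

#' Parse and format censored MIC values
#'
#' MIC cells are printed as a plain number for an exact call (`"2.5"`), as
#' `"<"` + lowest rung for growth inhibited already at the lowest tested
#' concentration (`"<0.5"`: the true MIC lies below the ladder), and as `">"`
#' + highest rung for growth still present at the highest concentration
#' (`">50"`). `parse_mic()` and `format_mic()` are exact inverses over any
#' ladder. Numbers use `"."` as decimal separator; `"5.0"` and `"5"` are equal.
#'
#' @param x Character vector of MIC cells (whitespace tolerated, e.g. `"< 1"`).
#' @param ladder Optional ladder (ascending numeric); when given, exact values
#'   must sit on a rung and censored values on the matching end rung.
#' @return `parse_mic()`: tibble with columns `mic` (numeric, ug/ml) and
#'   `censor` (`"exact"`, `"below_lowest"`, `"above_highest"`).
#' @examples
#' parse_mic(c("<0.5", "2.5", ">50"), antibiotic_ladders()$streptomycin)
#' format_mic(c(0.5, 2.5, 50), c("below_lowest", "exact", "above_highest"))
#' @export
parse_mic <- function(x, ladder = NULL) {
  x <- gsub("\\s+", "", as.character(x))
  censor <- dplyr::case_when(
    startsWith(x, "<") ~ "below_lowest",
    startsWith(x, ">") ~ "above_highest",
    TRUE ~ "exact"
  )
  value <- suppressWarnings(as.numeric(sub("^[<>]", "", x)))
  if (any(is.na(value) & !is.na(x))) {
    abort(paste0("Unparseable MIC cell(s): ",
                 paste(unique(x[is.na(value) & !is.na(x)]), collapse = ", ")))
  }
  out <- tibble(mic = value, censor = censor)
  if (!is.null(ladder)) {
    validate_ladder(ladder)
    check_mic_ladder(out, ladder)
  }
  out
}

check_mic_ladder <- function(mics, ladder) {
  ok <- rep(TRUE, nrow(mics))
  ok[mics$censor == "below_lowest"] <-
    mics$mic[mics$censor == "below_lowest"] == min(ladder)
  ok[mics$censor == "above_highest"] <-
    mics$mic[mics$censor == "above_highest"] == max(ladder)
  exact <- mics$censor == "exact" & !is.na(mics$mic)
  ok[exact] <- mics$mic[exact] %in% ladder
  if (any(!ok, na.rm = TRUE)) {
    abort(paste0("MIC value(s) inconsistent with ladder: ",
                 paste(format_mic(mics$mic[!ok], mics$censor[!ok]), collapse = ", ")))
  }
  invisible(mics)
}

#' @rdname parse_mic
#' @param mic Numeric MIC values (ug/ml).
#' @param censor Character vector over `"exact"`, `"below_lowest"`,
#'   `"above_highest"` (recycled if length 1).
#' @export
format_mic <- function(mic, censor = "exact") {
  if (length(censor) == 1) censor <- rep(censor, length(mic))
  stopifnot(length(mic) == length(censor))
  bad <- !censor %in% c("exact", "below_lowest", "above_highest")
  if (any(bad)) {
    abort(paste0("Unknown censor flag(s): ", paste(unique(censor[bad]), collapse = ", ")))
  }
  prefix <- c(exact = "", below_lowest = "<", above_highest = ">")[censor]
  paste0(prefix, fmt_num(mic))
}
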