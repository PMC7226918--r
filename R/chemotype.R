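#' Linear retention index (LRI)
#'
#' Interpolates a GC retention time against an n-alkane reference series in
#' the van den Dool-Kratz linear form:
#' `LRI = 100 * (n + (t - t_n) / (t_{n+1} - t_n))`, where `t_n` and `t_{n+1}`
#' are the retention times of the alkanes with `n` and `n + 1` carbons
#' bracketing `t`. Retention times outside the series range are an error (no
#' extrapolation). The index is exact on every alkane point
#' (`lri(t_Cn) = 100 n`) and strictly increasing in `t`.
#'
#' @param alkanes Data frame with columns `carbon_number` (integer >= 5) and
#'   `retention_time` (minutes, strictly increasing with carbon number).
#' @param t_r Retention time(s) in minutes.
#' @return Numeric LRI value(s).
#' @examples
#' alk <- data.frame(carbon_number = 14:16, retention_time = c(20, 22, 24.5))
#' lri(alk, 21.3)  # 1465
#' @export
lri <- function(alkanes, t_r) {
  if (!all(c("carbon_number", "retention_time") %in% names(alkanes))) {
    abort("alkanes needs columns carbon_number and retention_time")
  }
  alkanes <- alkanes[order(alkanes$carbon_number), ]
  cn <- as.numeric(alkanes$carbon_number)
  rt <- as.numeric(alkanes$retention_time)
  if (nrow(alkanes) < 2 || any(cn < 5) || any(cn != round(cn))) {
    abort("carbon_number must be integers >= 5 (at least two alkanes)")
  }
  if (any(diff(cn) <= 0) || any(diff(rt) <= 0)) {
    abort("retention_time must be strictly increasing with carbon_number")
  }
  t_r <- as.numeric(t_r)
  if (any(t_r < min(rt) | t_r > max(rt))) {
    abort("Retention time outside the alkane series range (no extrapolation)")
  }
  idx <- pmin(findInterval(t_r, rt), length(rt) - 1L)
  100 * (cn[idx] + (cn[idx + 1] - cn[idx]) * (t_r - rt[idx]) / (rt[idx + 1] - rt[idx]))
}

.eo_classes <- c("monoterpene_hydrocarbon", "sesquiterpene_hydrocarbon",
                 "oxygenated_monoterpene", "oxygenated_sesquiterpene", "other")

# Built-in compound -> class dictionary covering the constituents named in
# the analysed oil's main composition; input tables may override via their
# own class column.
.eo_class_dictionary <- c(
  "germacrene D" = "sesquiterpene_hydrocarbon",
  "beta-caryophyllene" = "sesquiterpene_hydrocarbon",
  "4-terpineol" = "oxygenated_monoterpene",
  "caryophyllene oxide" = "oxygenated_sesquiterpene",
  "spathulenol" = "oxygenated_sesquiterpene"
)

validate_composition <- function(composition, tolerance = 0.5) {
  needed <- c("compound", "rel_abundance")
  if (!all(needed %in% names(composition))) {
    abort("composition needs columns compound and rel_abundance")
  }
  if (!"class" %in% names(composition)) {
    composition$class <- unname(.eo_class_dictionary[composition$compound])
  }
  composition$class[is.na(composition$class)] <- "other"
  bad <- setdiff(unique(composition$class), .eo_classes)
  if (length(bad) > 0) {
    abort(paste0("Unknown compound class(es): ", paste(bad, collapse = ", ")))
  }
  ab <- as.numeric(composition$rel_abundance)
  if (any(is.na(ab) | ab < 0 | ab > 100)) {
    abort("rel_abundance must lie in [0, 100]")
  }
  if (sum(ab) > 100 + tolerance) {
    abort("Composition abundances exceed 100%")
  }
  composition$rel_abundance <- ab
  composition
}

#' Read an essential-oil composition table
#'
#' @param path CSV with columns `compound`, `class`, `rel_abundance` and
#'   optionally `retention_time` (minutes). Missing classes are filled from a
#'   small built-in dictionary, defaulting to `"other"`.
#' @return Validated tibble.
#' @export
read_eo_composition <- function(path) {
  validate_composition(read_table_dialect(path, "csv") |>
                         mutate(rel_abundance = as.numeric(.data$rel_abundance)))
}

#' Per-class abundance totals of an essential-oil composition
#'
#' Sums relative abundances per compound class and derives the grouped
#' totals: terpene hydrocarbons (mono- + sesquiterpene hydrocarbons) and
#' oxygenated terpenes (oxygenated mono- + sesquiterpenes). Mass is
#' conserved: the class totals sum to the composition total.
#'
#' @param composition Composition tibble (`compound`, `class`,
#'   `rel_abundance`).
#' @return List: `per_class` (named numeric over the five classes),
#'   `terpene_hydrocarbons`, `oxygenated`, `total`.
#' @export
class_totals <- function(composition) {
  if (nrow(composition) == 0) {
    per_class <- setNames(numeric(length(.eo_classes)), .eo_classes)
    return(list(per_class = per_class, terpene_hydrocarbons = 0,
                oxygenated = 0, total = 0))
  }
  composition <- validate_composition(composition)
  per_class <- vapply(.eo_classes, function(cl) {
    sum(composition$rel_abundance[composition$class == cl])
  }, numeric(1))
  list(
    per_class = per_class,
    terpene_hydrocarbons = per_class[["monoterpene_hydrocarbon"]] +
      per_class[["sesquiterpene_hydrocarbon"]],
    oxygenated = per_class[["oxygenated_monoterpene"]] +
      per_class[["oxygenated_sesquiterpene"]],
    total = sum(per_class)
  )
}

#' Chemotype label of an essential-oil composition
#'
#' The chemotype is named after the `k` most abundant constituents, joined
#' with `"/"` in descending abundance order (e.g. a germacrene
#' D/beta-caryophyllene chemotype). A tie at the k-th rank reports all tied
#' compounds (alphabetical among equals) and sets the `tie` attribute.
#'
#' @param composition Composition tibble.
#' @param k Number of leading compounds in the label (default 2).
#' @return Label string; attribute `tie` flags a tie at the cut.
#' @export
chemotype_label <- function(composition, k = 2) {
  composition <- validate_composition(composition)
  if (nrow(composition) == 0) abort("Composition is empty")
  if (k < 1) abort("k must be >= 1")
  ord <- order(-composition$rel_abundance, composition$compound)
  comp <- composition[ord, ]
  k <- min(k, nrow(comp))
  cut <- comp$rel_abundance[k]
  tied <- which(comp$rel_abundance == cut)
  # A tie at the cut rank makes the relative order of the tied compounds
  # arbitrary: all of them are reported (alphabetical among equals) and the
  # label is flagged.
  tie <- length(tied) >= 2
  label <- paste(comp$compound[seq_len(max(tied))], collapse = "/")
  attr(label, "tie") <- tie
  label
}
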