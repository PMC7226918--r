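#' Plant compartments of the screen
#'
#' The screen samples four compartments: three plant anatomical parts
#' (flower, leaf, stem) and the bulk soil near the roots. Strain identifiers
#' follow the `OV` convention: `OV` followed by the single-letter compartment
#' code (`F`, `L`, `S`, `T` for flower, leaf, stem and soil) and a number.
#'
#' @return `compartments()` returns a tibble with columns `label` and `code`.
#' @examples
#' compartments()
#' compartment_code("soil")
#' compartment_label("T")
#' @export
compartments <- function() {
  tibble::tibble(label = names(.compartment_codes),
                 code = unname(.compartment_codes))
}

.compartment_codes <- c(flower = "F", leaf = "L", stem = "S", soil = "T")

#' @rdname compartments
#' @param label Compartment label(s): `"flower"`, `"leaf"`, `"stem"`, `"soil"`.
#' @export
compartment_code <- function(label) {
  label <- as.character(label)
  bad <- setdiff(label, names(.compartment_codes))
  if (length(bad) > 0) {
    abort(paste0("Unknown compartment label(s): ", paste(bad, collapse = ", ")))
  }
  unname(.compartment_codes[label])
}

#' @rdname compartments
#' @param code Single-letter compartment code(s): `"F"`, `"L"`, `"S"`, `"T"`.
#' @export
compartment_label <- function(code) {
  code <- as.character(code)
  lookup <- setNames(names(.compartment_codes), .compartment_codes)
  bad <- setdiff(code, names(lookup))
  if (length(bad) > 0) {
    abort(paste0("Unknown compartment code(s): ", paste(bad, collapse = ", ")))
  }
  unname(lookup[code])
}

# Coerce labels or codes to a factor over the canonical compartment levels.
# Unknown values raise an error (with offending values named).
as_compartment <- function(x) {
  x <- as.character(x)
  out <- ifelse(x %in% .compartment_codes, compartment_label_safe(x), tolower(x))
  bad <- setdiff(out, names(.compartment_codes))
  if (length(bad) > 0) {
    abort(paste0("Unknown compartment(s): ", paste(unique(bad), collapse = ", ")))
  }
  factor(out, levels = names(.compartment_codes))
}

compartment_label_safe <- function(code) {
  lookup <- setNames(names(.compartment_codes), .compartment_codes)
  ifelse(code %in% names(lookup), lookup[code], code)
}
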