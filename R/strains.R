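# Explicit, versioned genus spelling-normalization map. Both variants occur in
# published culture-collection tables of this screen; unmapped names pass
# through unchanged.
.genus_spelling_map <- c(
  Sphyngomonas = "Sphingomonas",
  Rathaybacter = "Rathayibacter"
)

#' Normalize genus names
#'
#' Strips typographic markers (`*`, `_` italics markup), trims whitespace,
#' title-cases the name, and unifies known spelling variants
#' (Sphyngomonas/Sphingomonas, Rathaybacter/Rathayibacter). Names not in the
#' map pass through unchanged.
#'
#' @param x Character vector of genus names.
#' @return Character vector of normalized names.
#' @examples
#' normalize_genus(c("*Bacillus*", "sphyngomonas"))
#' @export
normalize_genus <- function(x) {
  x <- gsub("[*_]", "", as.character(x))
  x <- trimws(x)
  x <- ifelse(nchar(x) > 0,
              paste0(toupper(substr(x, 1, 1)), tolower(substring(x, 2))),
              x)
  mapped <- .genus_spelling_map[x]
  unname(ifelse(is.na(mapped), x, mapped))
}

#' Read a strain table
#'
#' Reads a table of isolates/strains with at least a strain identifier, a
#' compartment and a taxonomy (genus) column. Accepted header synonyms:
#' `strain` for `strain_id` and `taxonomy` for `genus`. Compartments may be
#' given as labels (`flower` ...) or single-letter codes (`F`/`L`/`S`/`T`).
#' Optional columns `species` and `gram` (`positive`/`negative`/`unknown`) are
#' carried through; `gram` defaults to `"unknown"`.
#'
#' Strain identifiers following the `OV` convention (`OVF10`, `OVT2`, ...)
#' must agree with the declared compartment; a mismatch is an error, which
#' catches transcription slips in fixtures.
#'
#' @param path Path to the table.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A tibble with columns `strain_id`, `compartment` (factor over
#'   flower/leaf/stem/soil), `genus` (normalized), `species`, `gram`.
#' @export
read_strain_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  df <- read_table_dialect(path, dialect)
  names(df) <- tolower(names(df))
  df <- dplyr::rename(df, dplyr::any_of(c(strain_id = "strain", genus = "taxonomy")))
  required <- c("strain_id", "compartment", "genus")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Strain table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0) {
    return(tibble(strain_id = character(), compartment = as_compartment(character()),
                  genus = character(), species = character(), gram = character()))
  }
  dup <- unique(df$strain_id[duplicated(df$strain_id)])
  if (length(dup) > 0) {
    abort(paste0("Duplicate strain_id: ", paste(dup, collapse = ", ")))
  }
  comp <- tryCatch(as_compartment(df$compartment), error = function(e) e)
  if (inherits(comp, "error")) {
    ok <- tolower(as.character(df$compartment)) %in% names(.compartment_codes) |
      as.character(df$compartment) %in% .compartment_codes
    abort(paste0("Unknown compartment in row(s): ",
                 paste(which(!ok), collapse = ", ")))
  }
  strains <- tibble(
    strain_id = as.character(df$strain_id),
    compartment = comp,
    genus = normalize_genus(df$genus),
    species = if ("species" %in% names(df)) as.character(df$species) else NA_character_,
    gram = if ("gram" %in% names(df)) tolower(as.character(df$gram)) else "unknown"
  )
  if (any(!is.na(strains$gram) & !strains$gram %in% c("positive", "negative", "unknown"))) {
    abort("gram must be one of: positive, negative, unknown")
  }
  strains$gram[is.na(strains$gram)] <- "unknown"
  if (any(!nzchar(strains$genus) | is.na(strains$genus))) {
    abort("genus must be non-empty for every strain")
  }
  check_ov_convention(strains)
  strains
}

# Strain ids following the OV<code><n> convention must match the declared
# compartment.
check_ov_convention <- function(strains) {
  follows <- grepl("^OV\\s?[FLST][0-9]+$", strains$strain_id)
  id_code <- sub("^OV\\s?([FLST])[0-9]+$", "\\1", strains$strain_id)
  declared <- compartment_code(as.character(strains$compartment))
  bad <- follows & id_code != declared
  if (any(bad)) {
    abort(paste0("Strain id/compartment mismatch: ",
                 paste(strains$strain_id[bad], collapse = ", ")))
  }
  invisible(strains)
}

read_table_dialect <- function(path, dialect) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  reader <- if (dialect == "csv") readr::read_csv else readr::read_tsv
  reader(path, col_types = readr::cols(.default = readr::col_character()),
         progress = FALSE, show_col_types = FALSE)
}

#' Read 16S marker sequences for strains
#'
#' Optional FASTA reader for marker sequences. Sequence names must match
#' strain identifiers in `strains` when supplied; sequences are carried as
#' opaque character metadata only (no alignment or classification is done).
#'
#' @param path Path to a FASTA file.
#' @param strains Optional strain table; when given, every sequence id must
#'   match a `strain_id`.
#' @return Tibble with columns `strain_id`, `sequence`.
#' @export
read_marker_fasta <- function(path, strains = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("read_marker_fasta() requires the Biostrings package")
  }
  seqs <- Biostrings::readDNAStringSet(path)
  out <- tibble(strain_id = sub("\\s.*$", "", names(seqs)),
                sequence = as.character(seqs))
  if (!is.null(strains)) {
    bad <- setdiff(out$strain_id, strains$strain_id)
    if (length(bad) > 0) {
      abort(paste0("FASTA id(s) not present in strain table: ",
                   paste(bad, collapse = ", ")))
    }
  }
  out
}
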