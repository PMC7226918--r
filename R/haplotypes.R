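#' Read RAPD band profiles
#'
#' Reads an isolate x band-size-bin matrix of 0/1 presence/absence calls.
#' The first column holds the isolate id; remaining columns are bins shared
#' by all isolates in the table.
#'
#' @param path Path to the table.
#' @param dialect `"tsv"` or `"csv"`.
#' @return Integer 0/1 matrix with isolate ids as row names.
#' @export
read_band_profiles <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  df <- read_table_dialect(path, dialect)
  if (ncol(df) < 2) abort("Band-profile table needs an id column plus bins")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate isolate id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  m <- as.matrix(df[-1])
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  validate_profiles(m)
}

validate_profiles <- function(profiles) {
  if (is.data.frame(profiles)) profiles <- as.matrix(profiles)
  if (!is.matrix(profiles) || is.null(rownames(profiles))) {
    abort("profiles must be a matrix with isolate ids as row names")
  }
  if (any(is.na(profiles)) || !all(profiles %in% c(0L, 1L))) {
    abort("Band profiles must be 0/1 with no missing values")
  }
  profiles
}

#' Bin raw band sizes into a shared schema
#'
#' Builds a presence/absence profile matrix from per-isolate lists of raw
#' band sizes (e.g. base pairs estimated from a gel). Sizes closer than
#' `tolerance` are merged into one bin by single-linkage; the default
#' tolerance of 0 keeps every distinct size as its own bin, matching exact
#' presence/absence comparison.
#'
#' @param band_sizes Named list: isolate id -> numeric vector of band sizes.
#' @param tolerance Maximum gap (same units as the sizes) merged into a bin.
#' @return 0/1 matrix (isolates x bins); bin columns named by mean size.
#' @export
build_band_bins <- function(band_sizes, tolerance = 0) {
  stopifnot(is.list(band_sizes), !is.null(names(band_sizes)), tolerance >= 0)
  sizes <- sort(unique(unlist(band_sizes)))
  if (length(sizes) == 0) abort("No band sizes supplied")
  bin_id <- cumsum(c(1, diff(sizes) > tolerance))
  centers <- tapply(sizes, bin_id, mean)
  m <- matrix(0L, length(band_sizes), length(centers),
              dimnames = list(names(band_sizes), fmt_num(as.numeric(centers))))
  for (iso in names(band_sizes)) {
    hits <- unique(bin_id[match(band_sizes[[iso]], sizes)])
    m[iso, hits] <- 1L
  }
  m
}

#' Dereplicate isolates into RAPD haplotypes
#'
#' Groups isolates whose band-profile vectors are exactly identical: each
#' distinct presence/absence pattern defines one haplotype, treated downstream
#' as a single strain. The member sets partition the input isolates.
#'
#' @param profiles 0/1 matrix (isolates x bins) as from
#'   [read_band_profiles()].
#' @return Tibble: `haplotype_id` (in order of first appearance), `members`
#'   (list of isolate ids), `size`.
#' @examples
#' m <- rbind(a = c(1, 0, 1), b = c(1, 0, 1), c = c(0, 1, 1))
#' dereplicate(m)
#' @export
dereplicate <- function(profiles) {
  profiles <- validate_profiles(profiles)
  key <- apply(profiles, 1, paste, collapse = "")
  first <- !duplicated(key)
  ids <- setNames(sprintf("H%03d", seq_len(sum(first))), key[first])
  tibble(
    haplotype_id = unname(ids[key[first]]),
    members = unname(split(rownames(profiles), factor(key, levels = key[first]))),
    size = as.integer(table(factor(key, levels = key[first])))
  )
}

#' Choose a haplotype's representative isolate
#'
#' For haplotypes with more than one member, one isolate is chosen at random
#' as the representative strain. The draw is uniform over members and
#' deterministic for a given seed; the caller's RNG state is untouched.
#'
#' @param members Character vector of member isolate ids (non-empty).
#' @param seed Integer seed.
#' @return One member id.
#' @export
choose_representative <- function(members, seed) {
  members <- as.character(members)
  if (length(members) == 0) abort("Haplotype has no members")
  if (length(members) == 1) return(members)
  with_seed(seed, sort(members)[sample.int(length(members), 1)])
}

#' @rdname choose_representative
#' @param haplotypes Tibble from [dereplicate()].
#' @return `assign_representatives()`: the haplotype tibble with a
#'   `representative` column (per-haplotype sub-seeds derived from `seed`).
#' @export
assign_representatives <- function(haplotypes, seed) {
  haplotypes |>
    mutate(representative = purrr::map2_chr(
      .data$members, seq_len(dplyr::n()),
      function(m, i) choose_representative(m, sub_seed(seed, i))
    ))
}

#' Haplotype distribution and sharing across compartments
#'
#' A haplotype counts in every compartment where it has a member. Reports
#' per-compartment haplotype counts, the pairwise shared-haplotype matrix,
#' the total number of distinct haplotypes, the number shared by two or more
#' compartments, and the shared fraction as a percentage rounded to one
#' decimal.
#'
#' @param haplotypes Tibble from [dereplicate()] (a `representative` column
#'   is carried through if present).
#' @param strains Strain table resolving every member isolate to a
#'   compartment.
#' @return List: `per_compartment` (named counts), `pairwise` (shared-count
#'   matrix), `total`, `shared`, `shared_pct`, and the per-haplotype
#'   `haplotypes` tibble with a `compartments` list-column.
#' @export
haplotype_summary <- function(haplotypes, strains) {
  comp <- setNames(as.character(strains$compartment), strains$strain_id)
  members <- unlist(haplotypes$members)
  unresolved <- setdiff(members, names(comp))
  if (length(unresolved) > 0) {
    abort(paste0("Member isolate(s) without compartment: ",
                 paste(unresolved, collapse = ", ")))
  }
  hap <- haplotypes |>
    mutate(compartments = purrr::map(.data$members,
                                     function(m) sort(unique(comp[m]))))
  levels_present <- names(.compartment_codes)
  per_compartment <- vapply(levels_present, function(cc) {
    sum(vapply(hap$compartments, function(s) cc %in% s, logical(1)))
  }, integer(1))
  pairwise <- matrix(0L, 4, 4, dimnames = list(levels_present, levels_present))
  for (i in 1:3) for (j in (i + 1):4) {
    a <- levels_present[i]; b <- levels_present[j]
    pairwise[i, j] <- sum(vapply(hap$compartments,
                                 function(s) a %in% s && b %in% s, logical(1)))
  }
  shared <- sum(vapply(hap$compartments, function(s) length(s) >= 2, logical(1)))
  total <- nrow(hap)
  list(
    per_compartment = per_compartment,
    pairwise = pairwise,
    total = total,
    shared = as.integer(shared),
    shared_pct = round(shared / total * 100, 1),
    haplotypes = hap
  )
}
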