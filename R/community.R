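# Taxon labels per strain at a rank; records without an annotation at that
# rank are dropped (their count is reported via attr "n_excluded").
rank_taxa <- function(strains, rank = c("genus", "species")) {
  rank <- match.arg(rank)
  taxa <- strains[[rank]] %||% rep(NA_character_, nrow(strains))
  keep <- !is.na(taxa) & nzchar(taxa)
  out <- tibble(taxon = taxa[keep],
                compartment = as.character(strains$compartment)[keep])
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Taxon richness
#'
#' Number of distinct (normalized) taxa at a rank, in one compartment or
#' overall. Records lacking an annotation at the rank (e.g. strains without a
#' species call) are excluded; their count is available as attribute
#' `n_excluded` on the result.
#'
#' @param strains Strain table (see [read_strain_table()]).
#' @param rank `"genus"` or `"species"`.
#' @param compartment Optional compartment label; omit for overall richness.
#' @return Integer count.
#' @export
richness <- function(strains, rank = c("genus", "species"), compartment = NULL) {
  tx <- rank_taxa(strains, rank)
  if (!is.null(compartment)) {
    compartment <- as.character(as_compartment(compartment))
    tx <- tx[tx$compartment == compartment, ]
  }
  out <- length(unique(tx$taxon))
  attr(out, "n_excluded") <- attr(tx, "n_excluded")
  out
}

#' Taxa shared between two compartments
#'
#' Taxa present in both compartments, counting any higher-order sharing
#' (a taxon found in three or four compartments is included in every pair it
#' covers).
#'
#' @inheritParams richness
#' @param a,b Distinct compartment labels.
#' @return Sorted character vector of shared taxa.
#' @export
pairwise_shared <- function(strains, rank = c("genus", "species"), a, b) {
  a <- as.character(as_compartment(a))
  b <- as.character(as_compartment(b))
  if (a == b) abort("Compartments must differ")
  tx <- rank_taxa(strains, rank)
  sort(intersect(unique(tx$taxon[tx$compartment == a]),
                 unique(tx$taxon[tx$compartment == b])))
}

#' Venn partition of taxa across compartments
#'
#' Assigns each taxon to exactly the subset of compartments in which it
#' occurs. Cells are keyed by the sorted compartment-code string (e.g.
#' `"F+L+S+T"` for taxa found everywhere, `"L+S"` for leaf-and-stem-only).
#' The derived statistic `shared_any` counts taxa in cells of subset size
#' two or more.
#'
#' @inheritParams richness
#' @return Tibble: `cell` (code string), `n_compartments`, `taxa`
#'   (list-column), `n`; attributes `shared_any` and `rank`.
#' @export
venn_partition <- function(strains, rank = c("genus", "species")) {
  rank <- match.arg(rank)
  tx <- rank_taxa(strains, rank)
  per_taxon <- tx |>
    distinct(.data$taxon, .data$compartment) |>
    group_by(.data$taxon) |>
    summarise(cell = paste(sort(compartment_code(.data$compartment)),
                           collapse = "+"),
              n_compartments = dplyr::n(), .groups = "drop")
  cells <- per_taxon |>
    group_by(.data$cell, .data$n_compartments) |>
    summarise(taxa = list(sort(.data$taxon)), n = dplyr::n(), .groups = "drop") |>
    arrange(dplyr::desc(.data$n_compartments), .data$cell)
  attr(cells, "shared_any") <- sum(per_taxon$n_compartments >= 2)
  attr(cells, "rank") <- rank
  cells
}

#' Sharing summary across ranks
#'
#' A compact report of distribution and sharing across the four
#' compartments: per-compartment counts, the pairwise shared matrix (upper
#' triangle), the total number of distinct taxa (or haplotypes), the number
#' shared by two or more compartments, and the shared percentage. The
#' percentage is rounded to the nearest integer for taxonomic ranks and to
#' one decimal for haplotypes, matching the usual reporting precision.
#'
#' @param strains Strain table.
#' @param haplotypes Optional haplotype tibble from [dereplicate()]; when
#'   given, a `"haplotype"` entry is included.
#' @param ranks Taxonomic ranks to summarize.
#' @return Named list of per-rank summaries, each a list with
#'   `per_compartment`, `pairwise`, `total`, `shared`, `shared_pct`.
#' @export
sharing_summary <- function(strains, haplotypes = NULL,
                            ranks = c("genus", "species")) {
  out <- list()
  for (rank in ranks) {
    tx <- rank_taxa(strains, rank)
    labs <- names(.compartment_codes)
    per_compartment <- vapply(labs, function(cc) {
      length(unique(tx$taxon[tx$compartment == cc]))
    }, integer(1))
    pairwise <- matrix(0L, 4, 4, dimnames = list(labs, labs))
    for (i in 1:3) for (j in (i + 1):4) {
      pairwise[i, j] <- length(pairwise_shared(strains, rank, labs[i], labs[j]))
    }
    vp <- venn_partition(strains, rank)
    total <- sum(vp$n)
    shared <- attr(vp, "shared_any")
    out[[rank]] <- list(per_compartment = per_compartment, pairwise = pairwise,
                        total = total, shared = shared,
                        shared_pct = round(shared / total * 100))
  }
  if (!is.null(haplotypes)) {
    out$haplotype <- haplotype_summary(haplotypes, strains)[
      c("per_compartment", "pairwise", "total", "shared", "shared_pct")]
  }
  out
}

#' Export a Venn partition as JSON
#'
#' @param partition Result of [venn_partition()].
#' @param path Output path.
#' @export
write_venn_json <- function(partition, path) {
  obj <- list(
    rank = attr(partition, "rank"),
    shared_any = attr(partition, "shared_any"),
    cells = setNames(partition$taxa, partition$cell)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
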