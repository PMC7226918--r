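#' Run the screening pipeline from a config
#'
#' Wires the analysis stages together: any subset of stages can be requested
#' by naming its input files in the config; only the stages with inputs are
#' run. Outputs (TSV/JSON) are written per stage under `out_dir`, together
#' with a run manifest recording inputs, seed, package version and option
#' flags. Re-running with the same config reproduces byte-identical TSV
#' outputs.
#'
#' Config keys (YAML file or list):
#' \describe{
#'   \item{seed}{integer, used for representative selection (default 1).}
#'   \item{haplotype}{`band_profiles` path (isolate x bin 0/1 table).}
#'   \item{community}{`strain_table` path.}
#'   \item{antibiogram}{either `growth_grades` (long grade table, calls MICs)
#'     or `mic_table` (pre-called wide table); optional `summaries`, a list of
#'     `{antibiotic, predicate, conc}` entries.}
#'   \item{antagonism}{`interactions` plus `strain_table`; optional
#'     `pathogens` metadata path.}
#'   \item{chemotype}{`composition` path; optional `alkanes` path to add LRI
#'     values for rows with a retention time.}
#' }
#'
#' @param config Path to a YAML config or an equivalent named list.
#' @param out_dir Output directory.
#' @return Named list of per-stage results (invisibly).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("Config not found: ", config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  results <- list()
  outputs <- character(0)

  need <- function(stage, key) {
    path <- config[[stage]][[key]]
    if (is.null(path)) {
      abort(paste0("Stage '", stage, "' requested without input '", key, "'"))
    }
    if (!file.exists(path)) {
      abort(paste0("Stage '", stage, "': input file not found: ", path))
    }
    path
  }
  emit_tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(df, path, progress = FALSE)
    outputs <<- c(outputs, path)
    path
  }
  emit_json <- function(obj, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    outputs <<- c(outputs, path)
    path
  }

  if (!is.null(config$haplotype)) {
    profiles <- read_band_profiles(need("haplotype", "band_profiles"))
    haps <- assign_representatives(dereplicate(profiles), seed)
    emit_tsv(
      haps |> mutate(members = purrr::map_chr(.data$members, paste, collapse = ",")),
      "haplotypes.tsv"
    )
    results$haplotype <- haps
    if (!is.null(config$haplotype$strain_table)) {
      strains <- read_strain_table(config$haplotype$strain_table)
      hs <- haplotype_summary(haps, strains)
      emit_json(hs[c("per_compartment", "total", "shared", "shared_pct")],
                "haplotype_summary.json")
      results$haplotype_summary <- hs
    }
  }

  if (!is.null(config$community)) {
    strains <- read_strain_table(need("community", "strain_table"))
    summary <- sharing_summary(strains)
    vp <- venn_partition(strains, "genus")
    emit_json(lapply(summary, function(s) {
      list(per_compartment = as.list(s$per_compartment), total = s$total,
           shared = s$shared, shared_pct = s$shared_pct)
    }), "community_summary.json")
    write_venn_json(vp, file.path(out_dir, "genus_venn.json"))
    outputs <- c(outputs, file.path(out_dir, "genus_venn.json"))
    results$community <- summary
  }

  if (!is.null(config$antibiogram)) {
    panel <- if (!is.null(config$antibiogram$mic_table)) {
      read_antibiogram(need("antibiogram", "mic_table"))
    } else {
      grades <- readr::read_tsv(need("antibiogram", "growth_grades"),
                                show_col_types = FALSE, progress = FALSE)
      call_mics(grades)
    }
    emit_tsv(resistance_table(panel), "resistance_table.tsv")
    sums <- lapply(config$antibiogram$summaries %||% list(), function(s) {
      r <- threshold_fraction(panel, s$antibiotic, s$predicate, s$conc)
      c(list(antibiotic = s$antibiotic, predicate = s$predicate, conc = s$conc), r)
    })
    if (length(sums) > 0) emit_json(sums, "antibiogram_summaries.json")
    results$antibiogram <- list(panel = panel, summaries = sums)
  }

  if (!is.null(config$antagonism)) {
    mat <- read_interaction_table(need("antagonism", "interactions"))
    strains <- read_strain_table(need("antagonism", "strain_table"))
    tsi_tab <- tsi(mat)
    cs <- compartment_scores(mat, strains)
    emit_tsv(tsi_tab, "tsi.tsv")
    emit_tsv(cs, "compartment_scores.tsv")
    emit_json(compartment_network(cs),
              "compartment_network.json")
    results$antagonism <- list(tsi = tsi_tab, compartment_scores = cs)
    if (!is.null(config$antagonism$pathogens)) {
      pathogens <- readr::read_tsv(config$antagonism$pathogens,
                                   show_col_types = FALSE, progress = FALSE)
      pps <- pathogen_panel_summary(mat, pathogens)
      emit_tsv(pps$per_tester, "pathogen_per_tester.tsv")
      emit_tsv(pps$per_gram, "pathogen_per_gram.tsv")
      results$pathogen_panel <- pps
    }
  }

  if (!is.null(config$chemotype)) {
    comp <- read_eo_composition(need("chemotype", "composition"))
    if (!is.null(config$chemotype$alkanes) && "retention_time" %in% names(comp)) {
      alk <- readr::read_csv(config$chemotype$alkanes, show_col_types = FALSE,
                             progress = FALSE)
      has_rt <- !is.na(comp$retention_time)
      comp$lri <- NA_real_
      comp$lri[has_rt] <- lri(alk, as.numeric(comp$retention_time[has_rt]))
    }
    ct <- class_totals(comp)
    label <- chemotype_label(comp)
    emit_json(list(class_totals = as.list(ct$per_class),
                   terpene_hydrocarbons = ct$terpene_hydrocarbons,
                   oxygenated = ct$oxygenated,
                   total = ct$total,
                   chemotype = as.character(label),
                   tie = isTRUE(attr(label, "tie"))),
              "chemotype_summary.json")
    results$chemotype <- list(composition = comp, class_totals = ct,
                              label = label)
  }

  manifest <- list(
    package = "cultscreen",
    version = as.character(utils::packageVersion("cultscreen")),
    seed = seed,
    inputs = config,
    outputs = basename(outputs)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

# Network export for compartment-level antagonism plots: nodes are
# compartments, weighted directed links are cross-compartment inhibitory
# flows, self-loops carry self-inhibition.
compartment_network <- function(scores) {
  list(
    nodes = lapply(seq_len(nrow(scores)), function(i) {
      list(id = as.character(scores$compartment[i]),
           inhibitory_sum = scores$inhibitory_sum[i],
           sensitivity_sum = scores$sensitivity_sum[i],
           inhibition_potential = scores$inhibition_potential[i])
    }),
    self_loops = lapply(seq_len(nrow(scores)), function(i) {
      list(id = as.character(scores$compartment[i]),
           self_inhibition_sum = scores$self_inhibition_sum[i])
    })
  )
}
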