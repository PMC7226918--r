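#' Simulation configuration
#'
#' Defines the study conditions emulated by the generators. Defaults mirror
#' the screen's scale: four compartments with (16, 17, 19, 12) strains
#' (flower, leaf, stem, soil) dereplicated from (24, 24, 25, 24) isolates, a
#' genus pool of 19 with about a third of genera occurring in two or more
#' compartments, two haplotypes shared between leaf and stem, six antibiotics
#' on their concentration ladders, 20 band-size bins, and cross-compartment
#' inhibition more probable than within-compartment inhibition with a
#' decreasing tester gradient soil > stem > leaf > flower.
#'
#' One global `seed` fans out to independent per-generator streams, so adding
#' or re-running one generator never perturbs the output of another.
#'
#' @param seed Integer global seed.
#' @param strains_per_compartment Named integer vector of dereplicated strain
#'   counts per compartment.
#' @param isolates_per_compartment Named integer vector of raw isolate counts
#'   (>= strains_per_compartment).
#' @param genus_pool_size Number of genera in the pool.
#' @param genus_sharing_rate Probability that a genus is assigned to two or
#'   more compartments (expected shared fraction).
#' @param n_shared_haplotypes Haplotypes shared between `shared_pair`.
#' @param shared_pair Two compartment labels sharing haplotypes.
#' @param band_bins Number of band-size bins in RAPD profiles.
#' @param ladders Named list of antibiotic concentration ladders.
#' @param planted_mic_mass Length-3 numeric: probability mass on
#'   (below_lowest, exact, above_highest) for planted MICs; exact mass is
#'   spread uniformly over rungs 2..top (an exact MIC at the lowest rung is
#'   indistinguishable from left censoring, so it is never planted).
#' @param grade_noise_p Per-cell probability that one random rung's growth
#'   reading is flipped.
#' @param p_within Within-compartment inhibition probability.
#' @param p_cross Cross-compartment inhibition probability of a tester, as a
#'   single number or a named per-compartment vector (the planted inhibitory
#'   ordering is descending `p_cross`).
#' @param score_weights Sampling weights over scores 1, 2, 3 when inhibiting.
#' @param nd_rate Fraction of cells reported as not determined (`Nd`).
#' @return A `sim_config` list (validated).
#' @export
sim_config <- function(seed = 1,
                       strains_per_compartment = c(flower = 16, leaf = 17,
                                                   stem = 19, soil = 12),
                       isolates_per_compartment = c(flower = 24, leaf = 24,
                                                    stem = 25, soil = 24),
                       genus_pool_size = 19,
                       genus_sharing_rate = 0.37,
                       n_shared_haplotypes = 2,
                       shared_pair = c("leaf", "stem"),
                       band_bins = 20,
                       ladders = antibiotic_ladders(),
                       planted_mic_mass = c(0.3, 0.5, 0.2),
                       grade_noise_p = 0,
                       p_within = 0.2,
                       p_cross = c(flower = 0.35, leaf = 0.5,
                                   stem = 0.65, soil = 0.8),
                       score_weights = c(1, 1, 1),
                       nd_rate = 0) {
  comps <- names(strains_per_compartment)
  if (is.null(comps) || !all(comps %in% names(.compartment_codes))) {
    abort("strains_per_compartment must be named by compartment label")
  }
  stopifnot(all(strains_per_compartment >= 1),
            all(isolates_per_compartment[comps] >= strains_per_compartment),
            genus_pool_size >= 1,
            genus_sharing_rate >= 0, genus_sharing_rate <= 1,
            grade_noise_p >= 0, grade_noise_p <= 1,
            p_within >= 0, p_within <= 1,
            all(p_cross >= 0), all(p_cross <= 1),
            nd_rate >= 0, nd_rate < 1,
            length(score_weights) == 3, all(score_weights >= 0),
            length(planted_mic_mass) == 3, all(planted_mic_mass >= 0),
            sum(planted_mic_mass) > 0)
  if (length(p_cross) == 1) {
    p_cross <- setNames(rep(p_cross, length(comps)), comps)
  }
  if (!all(comps %in% names(p_cross))) {
    abort("p_cross must cover every compartment (or be a single number)")
  }
  if (n_shared_haplotypes > 0 &&
      (length(shared_pair) != 2 || !all(shared_pair %in% comps))) {
    abort("shared_pair must name two configured compartments")
  }
  structure(list(seed = as.integer(seed),
                 strains_per_compartment = strains_per_compartment,
                 isolates_per_compartment = isolates_per_compartment[comps],
                 genus_pool_size = genus_pool_size,
                 genus_sharing_rate = genus_sharing_rate,
                 n_shared_haplotypes = n_shared_haplotypes,
                 shared_pair = shared_pair,
                 band_bins = band_bins,
                 ladders = ladders,
                 planted_mic_mass = planted_mic_mass / sum(planted_mic_mass),
                 grade_noise_p = grade_noise_p,
                 p_within = p_within,
                 p_cross = p_cross[comps],
                 score_weights = score_weights,
                 nd_rate = nd_rate),
            class = "sim_config")
}

#' Generate a synthetic strain table
#'
#' Draws per-compartment genus pools such that the expected fraction of
#' genera occurring in two or more compartments matches `genus_sharing_rate`,
#' then assigns strains to genera. Every genus in a compartment's pool is
#' observed at least once when capacity allows, so pool-level sharing is
#' realized in the observed table. Deterministic per seed.
#'
#' @param config A [sim_config()].
#' @return Strain tibble (`strain_id`, `compartment`, `genus`, `species`,
#'   `gram`); attribute `truth` holds the genus-to-compartment pools.
#' @export
gen_strains <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  comps <- names(config$strains_per_compartment)
  with_seed(sub_seed(config$seed, 101), {
    genera <- sprintf("Genus%02d", seq_len(config$genus_pool_size))
    gram <- setNames(sample(c("positive", "negative"),
                            length(genera), replace = TRUE), genera)
    assignment <- lapply(genera, function(g) {
      if (length(comps) >= 2 && runif(1) < config$genus_sharing_rate) {
        size <- resample(2:length(comps))
      } else {
        size <- 1
      }
      sort(resample(comps, size))
    })
    names(assignment) <- genera
    pools <- lapply(setNames(comps, comps), function(cc) {
      genera[vapply(assignment, function(s) cc %in% s, logical(1))]
    })
    # every compartment needs a non-empty pool; repair by *moving* a
    # single-compartment genus out of a crowded pool so a sharing rate of 0
    # still yields zero shared genera
    for (cc in comps) {
      if (length(pools[[cc]]) == 0) {
        donor <- NULL
        for (g in sample(genera)) {
          if (length(assignment[[g]]) == 1 &&
              length(pools[[assignment[[g]]]]) >= 2) {
            donor <- g
            break
          }
        }
        if (is.null(donor)) donor <- sample(genera, 1)
        pools[[assignment[[donor]][1]]] <-
          setdiff(pools[[assignment[[donor]][1]]], donor)
        assignment[[donor]] <- cc
        pools[[cc]] <- c(pools[[cc]], donor)
      }
    }
    strains <- purrr::map_dfr(comps, function(cc) {
      n <- config$strains_per_compartment[[cc]]
      pool <- pools[[cc]]
      picks <- if (n >= length(pool)) {
        c(pool, resample(pool, n - length(pool), replace = TRUE))
      } else {
        resample(pool, n)
      }
      tibble(strain_id = paste0("OV", compartment_code(cc), seq_len(n)),
             compartment = cc,
             genus = sample(picks),
             species = NA_character_)
    })
    strains$species <- paste0(tolower(strains$genus), " sp.")
    strains$gram <- unname(gram[strains$genus])
    strains$compartment <- as_compartment(strains$compartment)
    attr(strains, "truth") <- list(pools = pools, assignment = assignment)
    strains
  })
}

#' Generate synthetic RAPD band profiles
#'
#' Plants one distinct random band vector per haplotype, shares
#' `n_shared_haplotypes` of them between the `shared_pair` compartments, and
#' assigns isolates to haplotypes so that each compartment yields its
#' configured number of haplotypes from its configured number of isolates
#' (surplus isolates are clones of random haplotypes). With zero band noise
#' the planted haplotype count is exactly recoverable by [dereplicate()].
#'
#' @param config A [sim_config()].
#' @return 0/1 matrix of isolates x bins; attribute `truth` lists planted
#'   haplotype memberships and the planted distinct count.
#' @export
gen_band_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  comps <- names(config$strains_per_compartment)
  n_hap <- config$strains_per_compartment
  n_shared <- config$n_shared_haplotypes
  total_hap <- sum(n_hap) - n_shared
  with_seed(sub_seed(config$seed, 202), {
    profiles <- matrix(0L, 0, config$band_bins)
    seen <- character(0)
    vecs <- vector("list", total_hap)
    for (i in seq_len(total_hap)) {
      repeat {
        v <- as.integer(runif(config$band_bins) < 0.5)
        key <- paste(v, collapse = "")
        if (!key %in% seen) break
      }
      seen <- c(seen, key)
      vecs[[i]] <- v
    }
    # allocate haplotypes: shared ones first, then compartment-private ones
    shared_ids <- seq_len(n_shared)
    idx <- n_shared
    private <- lapply(setNames(comps, comps), function(cc) integer(0))
    for (cc in comps) {
      n_priv <- n_hap[[cc]] - if (cc %in% config$shared_pair) n_shared else 0
      private[[cc]] <- idx + seq_len(n_priv)
      idx <- idx + n_priv
    }
    stopifnot(idx == total_hap)
    members <- lapply(seq_len(total_hap), function(i) character(0))
    for (cc in comps) {
      haps <- c(if (cc %in% config$shared_pair) shared_ids else integer(0),
                private[[cc]])
      m <- config$isolates_per_compartment[[cc]]
      owner <- c(haps, resample(haps, m - length(haps), replace = TRUE))
      iso <- paste0("OV", compartment_code(cc), "i", seq_len(m))
      for (k in seq_along(iso)) {
        members[[owner[k]]] <- c(members[[owner[k]]], iso[k])
      }
    }
    mat <- do.call(rbind, lapply(seq_len(total_hap), function(i) {
      do.call(rbind, rep(list(vecs[[i]]), length(members[[i]])))
    }))
    rownames(mat) <- unlist(members)
    colnames(mat) <- paste0("bin", seq_len(config$band_bins))
    mat <- mat[sample(nrow(mat)), , drop = FALSE]
    attr(mat, "truth") <- list(n_haplotypes = total_hap, members = members)
    mat
  })
}

#' Generate synthetic growth-grade series with planted MICs
#'
#' For each strain x antibiotic cell a true (possibly censored) MIC is drawn
#' from `planted_mic_mass`; grades are growth below the MIC and `none` at and
#' above it (all-`none` for left censoring, growth everywhere for right
#' censoring). With probability `grade_noise_p` one random rung's reading is
#' flipped.
#'
#' @param config A [sim_config()].
#' @param strains Strain table (ids used for the cells).
#' @return List: `grades` (long tibble `strain_id`, `antibiotic`,
#'   `concentration`, `grade`) and `truth` (tibble `strain_id`, `antibiotic`,
#'   `mic`, `censor`).
#' @export
gen_growth_grades <- function(config, strains) {
  stopifnot(inherits(config, "sim_config"))
  growth_pool <- c("complete", "strong", "weak", "very_weak")
  with_seed(sub_seed(config$seed, 303), {
    cells <- tidyr::expand_grid(strain_id = strains$strain_id,
                                antibiotic = names(config$ladders))
    res <- purrr::pmap(cells, function(strain_id, antibiotic) {
      ladder <- config$ladders[[antibiotic]]
      kind <- sample(c("below_lowest", "exact", "above_highest"), 1,
                     prob = config$planted_mic_mass)
      mic <- switch(kind,
        below_lowest = min(ladder),
        above_highest = max(ladder),
        exact = resample(ladder[-1])
      )
      growth <- switch(kind,
        below_lowest = rep(FALSE, length(ladder)),
        above_highest = rep(TRUE, length(ladder)),
        exact = ladder < mic
      )
      if (runif(1) < config$grade_noise_p) {
        flip <- sample.int(length(ladder), 1)
        growth[flip] <- !growth[flip]
      }
      grade <- ifelse(growth, sample(growth_pool, length(ladder), replace = TRUE),
                      "none")
      list(
        grades = tibble(strain_id = strain_id, antibiotic = antibiotic,
                        concentration = ladder, grade = grade),
        truth = tibble(strain_id = strain_id, antibiotic = antibiotic,
                       mic = mic, censor = kind)
      )
    })
    list(grades = purrr::map_dfr(res, "grades"),
         truth = purrr::map_dfr(res, "truth"))
  })
}

#' Generate a synthetic cross-streak interaction matrix
#'
#' Each tester x target cell inhibits with probability `p_cross[tester's
#' compartment]` when the two strains come from different compartments and
#' `p_within` when they share one; inhibiting cells draw their score from
#' `score_weights` over 1-3, others score 0. A fraction `nd_rate` of cells is
#' masked as not determined. Self-pairs (a strain against itself) are not
#' generated. The planted inhibitory ordering (compartments by descending
#' `p_cross`) is attached as truth when the probabilities are distinct.
#'
#' @param config A [sim_config()].
#' @param strains Strain table (testers, and targets if `targets` is `NULL`).
#' @param targets Optional pathogen-panel tibble (`target_id`, `group`,
#'   `gram`); all tester-target pairs are then cross-compartment.
#' @return An [interaction_matrix()]; attribute `truth` holds the generating
#'   parameters and planted ordering.
#' @export
gen_interaction_matrix <- function(config, strains, targets = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(sub_seed(config$seed, 404), {
    comp <- setNames(as.character(strains$compartment), strains$strain_id)
    target_ids <- if (is.null(targets)) strains$strain_id else targets$target_id
    pairs <- tidyr::expand_grid(tester = strains$strain_id, target = target_ids)
    pairs <- pairs[pairs$tester != pairs$target, ]
    same <- if (is.null(targets)) {
      comp[pairs$tester] == comp[pairs$target]
    } else {
      rep(FALSE, nrow(pairs))
    }
    p <- ifelse(same, config$p_within, config$p_cross[comp[pairs$tester]])
    inhibits <- runif(nrow(pairs)) < p
    score <- integer(nrow(pairs))
    score[inhibits] <- sample(1:3, sum(inhibits), replace = TRUE,
                              prob = config$score_weights)
    nd <- runif(nrow(pairs)) < config$nd_rate
    pairs$score <- ifelse(nd, "Nd", as.character(score))
    mat <- interaction_matrix(pairs, testers = strains$strain_id,
                              targets = target_ids)
    ordering <- if (anyDuplicated(config$p_cross) == 0) {
      names(sort(config$p_cross, decreasing = TRUE))
    } else NULL
    attr(mat, "truth") <- list(p_within = config$p_within,
                               p_cross = config$p_cross,
                               planted_inhibitory_ordering = ordering)
    mat
  })
}

#' Write a full synthetic input bundle
#'
#' Runs every generator and writes the TSV inputs consumed by the pipeline
#' plus a JSON truth file alongside.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths (invisibly).
#' @export
simulate_bundle <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  strains <- gen_strains(config)
  bands <- gen_band_profiles(config)
  growth <- gen_growth_grades(config, strains)
  inter <- gen_interaction_matrix(config, strains)
  paths <- list(
    strains = file.path(dir, "strains.tsv"),
    band_profiles = file.path(dir, "band_profiles.tsv"),
    growth_grades = file.path(dir, "growth_grades.tsv"),
    interactions = file.path(dir, "interactions.tsv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_tsv(strains, paths$strains, progress = FALSE)
  readr::write_tsv(tibble::as_tibble(bands, rownames = "isolate_id"),
                   paths$band_profiles, progress = FALSE)
  readr::write_tsv(growth$grades, paths$growth_grades, progress = FALSE)
  write_interaction_table(inter, paths$interactions)
  truth <- list(
    seed = config$seed,
    genus_pools = attr(strains, "truth")$pools,
    n_haplotypes = attr(bands, "truth")$n_haplotypes,
    planted_mics = growth$truth,
    interaction = attr(inter, "truth")
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
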