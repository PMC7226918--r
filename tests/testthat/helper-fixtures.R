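fixture_path <- function(name) {
  system.file("extdata", name, package = "cultscreen", mustWork = TRUE)
}

published_panel <- function() {
  read_antibiogram(fixture_path("oregano_strain_mic.tsv"))
}

published_strains <- function() {
  read_strain_table(fixture_path("oregano_strain_mic.tsv"))
}

write_tsv_fixture <- function(df) {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(df, path, progress = FALSE)
  path
}

# Independent brute-force dereplication oracle: transitive closure of
# pairwise vector equality, via repeated merging of singleton groups.
brute_force_partition <- function(profiles) {
  n <- nrow(profiles)
  group <- seq_len(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && all(profiles[i, ] == profiles[j, ])) {
        old <- group[j]
        group[group == old] <- group[i]
      }
    }
  }
  unname(split(rownames(profiles), group))
}

# Band-profile matrix that plants the published haplotype structure:
# 16 flower-only, 15 leaf-only, 17 stem-only, 12 soil-only and 2 haplotypes
# with one leaf and one stem member each, giving per-compartment counts
# (16, 17, 19, 12) and 62 distinct haplotypes.
published_haplotype_profiles <- function(bins = 12) {
  n_hap <- 62
  stopifnot(2^bins > n_hap)
  vecs <- t(sapply(seq_len(n_hap), function(i) {
    as.integer(intToBits(i))[seq_len(bins)]
  }))
  members <- c(paste0("OVF", 1:16),          # haplotypes 1..16: flower
               paste0("OVL", 1:15),          # 17..31: leaf only
               paste0("OVS", 1:17),          # 32..48: stem only
               paste0("OVT", 1:12),          # 49..60: soil
               "OVL16", "OVS18",             # 61: shared leaf/stem
               "OVL17", "OVS19")             # 62: shared leaf/stem
  owner <- c(1:60, 61, 61, 62, 62)
  m <- vecs[owner, ]
  rownames(m) <- members
  colnames(m) <- paste0("bin", seq_len(bins))
  m
}

published_haplotype_strains <- function() {
  m <- published_haplotype_profiles()
  ids <- rownames(m)
  tibble::tibble(
    strain_id = ids,
    compartment = compartment_label(substr(ids, 3, 3)),
    genus = "Genus01"
  )
}

# Hand-computed two-compartment toy matrix for compartment aggregation:
# A testers {a1, a2}, B targets {b1, b2}; cross a->b = (3, 2, 1, 0),
# b->a = (1, 1, 0, 0), within-A (2, 0), within-B (0, 0).
toy_compartment_matrix <- function() {
  df <- data.frame(
    tester = c("a1", "a1", "a2", "a2",  "b1", "b1", "b2", "b2",
               "a1", "a2", "b1", "b2"),
    target = c("b1", "b2", "b1", "b2",  "a1", "a2", "a1", "a2",
               "a2", "a1", "b2", "b1"),
    score  = c(3, 2, 1, 0,  1, 1, 0, 0,  2, 0, 0, 0)
  )
  strains <- tibble::tibble(
    strain_id = c("a1", "a2", "b1", "b2"),
    compartment = c("flower", "flower", "soil", "soil"),
    genus = "Genus01"
  )
  list(matrix = interaction_matrix(df), strains = strains)
}

# Random interaction matrix over random compartments, for conservation
# properties.
random_interaction_case <- function(seed, n_strains = 12, nd_rate = 0.1) {
  set.seed(seed)
  ids <- paste0("st", seq_len(n_strains))
  strains <- tibble::tibble(
    strain_id = ids,
    compartment = sample(c("flower", "leaf", "stem", "soil"), n_strains,
                         replace = TRUE),
    genus = "Genus01"
  )
  df <- expand.grid(tester = ids, target = ids, stringsAsFactors = FALSE)
  df <- df[df$tester != df$target, ]
  df$score <- sample(0:3, nrow(df), replace = TRUE)
  df$score[runif(nrow(df)) < nd_rate] <- "Nd"
  list(matrix = interaction_matrix(df), strains = strains, long = df)
}
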