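# small in-code fixtures shared across test files

# one-row sync helper: counts in A,T,C,G,N,del order
site1 <- function(c1, c2, scaffold = "scaf1", position = 42L, ref = "A") {
  sync_sites(scaffold, position, ref,
             matrix(as.integer(c1), 1L), matrix(as.integer(c2), 1L))
}

# random valid sync sites for round-trip / property tests
random_sync <- function(n, seed = 1L) {
  withr::with_seed(seed, {
    sync_sites(
      scaffold = sample(c("scafA", "scafB"), n, replace = TRUE),
      position = sample.int(1e6L, n),
      ref = sample(c("A", "C", "G", "T", "N"), n, replace = TRUE),
      counts1 = matrix(rpois(6L * n, 8), n, 6L),
      counts2 = matrix(rpois(6L * n, 8), n, 6L))
  })
}

# a hand-laid two-gene annotation on one scaffold
tiny_genes <- function() {
  gene_models(
    gene_id = c("g1", "g1", "g2"),
    scaffold = "scaf1",
    strand = c("+", "+", "-"),
    start = c(100L, 300L, 1000L),
    end = c(200L, 400L, 1500L))
}

# a tidy cell-count table: 2 individuals x 2 replicates x 2 types
tiny_counts <- function() {
  tibble::tibble(
    individual_id = rep(c("L1", "L2"), each = 4L),
    population = rep(c("north", "south"), each = 4L),
    sex = rep(c("F", "M"), each = 4L),
    replicate_id = rep(rep(c("r1", "r2"), each = 2L), 2L),
    cell_type = rep(c("granulocyte", "plasmatocyte"), 4L),
    n_total = c(5L, 1L, 3L, 1L, 10L, 4L, 6L, 2L),
    n_phagocytic = c(4L, 1L, 2L, 1L, 5L, 1L, 3L, 0L))
}

# independent brute-force Nei FST used as the oracle: plain arithmetic,
# no shared code with the package internals
oracle_fst <- function(p1, p2) {
  h1 <- 1 - p1^2 - (1 - p1)^2
  h2 <- 1 - p2^2 - (1 - p2)^2
  hw <- (h1 + h2) / 2
  pb <- (p1 + p2) / 2
  ht <- 1 - pb^2 - (1 - pb)^2
  (ht - hw) / ht
}

oracle_region_fst <- function(p1, p2) {
  ht <- 1 - ((p1 + p2) / 2)^2 - (1 - (p1 + p2) / 2)^2
  hw <- ((1 - p1^2 - (1 - p1)^2) + (1 - p2^2 - (1 - p2)^2)) / 2
  (sum(ht) - sum(hw)) / sum(ht)
}
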