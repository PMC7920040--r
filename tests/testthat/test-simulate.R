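test_that("generators are pure functions of config and seed", {
  cfg <- sim_config(scaffold_length = 2e5, n_genes = 60L, n_candidates = 5L,
                    n_terms = 10L)
  a1 <- simulate_annotation(cfg, seed = 42L)
  a2 <- simulate_annotation(cfg, seed = 42L)
  expect_identical(a1, a2)
  d1 <- simulate_divergence(cfg, a1, seed = 42L)
  d2 <- simulate_divergence(cfg, a1, seed = 42L)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_sync(d1$sites, f1); write_sync(d2$sites, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(d1$truth$q1,
                         simulate_divergence(cfg, a1, seed = 43L)$truth$q1))
  c1 <- simulate_cohort(cohort_config(n_per_group = 3L), seed = 7L)
  c2 <- simulate_cohort(cohort_config(n_per_group = 3L), seed = 7L)
  expect_identical(c1$counts, c2$counts)
})

test_that("simulated annotations are valid and candidates are genes", {
  cfg <- sim_config(scaffold_length = 5e5, n_genes = 120L, n_candidates = 12L)
  ann <- simulate_annotation(cfg, seed = 2L)
  expect_true(all(ann$genes$start >= 0L))
  expect_true(all(ann$genes$end <= ann$scaffold_lengths[ann$genes$scaffold]))
  expect_true(all(ann$candidates %in% ann$genes$gene_id))
  expect_length(ann$candidates, 12L)
  expect_length(unique(ann$genes$gene_id), 120L)
  # gene placement refuses impossible densities
  expect_error(simulate_annotation(sim_config(scaffold_length = 1e4,
                                              n_genes = 500L), seed = 1L),
               "capacity")
  # the candidate term is present in the term map at candidate-set size
  expect_setequal(ann$terms[["custom:phagocytosis"]], ann$candidates)
})

test_that("near-zero divergence collapses both populations onto the ancestor", {
  cfg <- sim_config(n_scaffolds = 1L, scaffold_length = 4e5,
                    snp_density = 0.005, monomorphic_density = 0,
                    background_F = 1e-6, mean_depth = 1000)
  div <- simulate_divergence(cfg, seed = 31L)
  expect_lt(max(abs(div$truth$q1 - div$truth$p_anc)), 1e-2)
  expect_lt(max(abs(div$truth$q2 - div$truth$p_anc)), 1e-2)
  snps <- call_snps(div$sites, snp_filter(max_coverage = 2000L))
  expect_gt(nrow(snps), 1000L)
  expect_lt(mean(snps$fst), 0.01)
})

test_that("estimated divergence tracks a truth-matched expectation at modest n", {
  cfg <- sim_config(n_scaffolds = 1L, scaffold_length = 2e6,
                    snp_density = 0.01, monomorphic_density = 0,
                    background_F = 0.05)
  div <- simulate_divergence(cfg, seed = 14L)
  snps <- call_snps(div$sites)
  # independent Monte-Carlo oracle from the recorded truth frequencies
  oracle <- withr::with_seed(999L, {
    q1 <- div$truth$q1; q2 <- div$truth$q2; n <- length(q1)
    x1 <- rbinom(n, 100L, q1) / 100; x2 <- rbinom(n, 100L, q2) / 100
    d1 <- rpois(n, 100); d2 <- rpois(n, 100)
    a1 <- rbinom(n, d1, x1); a2 <- rbinom(n, d2, x2)
    minor <- pmin(a1 + a2, (d1 - a1) + (d2 - a2))
    keep <- d1 >= 10 & d2 >= 10 & d1 <= 500 & d2 <= 500 & minor >= 2
    mean(oracle_fst(a1[keep] / d1[keep], a2[keep] / d2[keep]))
  })
  expect_lt(abs(mean(snps$fst) - oracle), 0.02)
})

test_that("monomorphic filler sites carry reference-only reads", {
  cfg <- sim_config(n_scaffolds = 1L, scaffold_length = 1e5,
                    snp_density = 0.002, monomorphic_density = 0.002)
  div <- simulate_divergence(cfg, seed = 4L)
  snp_ids <- paste0(div$truth$scaffold, ":", div$truth$position)
  all_ids <- paste0(div$sites$scaffold, ":", div$sites$position)
  mono <- div$sites[!(all_ids %in% snp_ids), ]
  cov1 <- rowSums(as.matrix(mono[paste0(c("A", "T", "C", "G", "N", "del"), 1L)]))
  ref_count <- vapply(seq_len(nrow(mono)), function(i)
    mono[[paste0(mono$ref[i], 1L)]][i], integer(1))
  expect_equal(ref_count, as.integer(cov1))
})

test_that("extreme phagocytosis propensities propagate to the indices", {
  cc <- cohort_config(n_per_group = 4L,
                      propensity_population = c(north = 1, south = 1),
                      sex_logit_effect = 0, type_logit_effect = c(
                        granulocyte = 0, plasmatocyte = 0, oenocytoid = 0,
                        other = 0))
  sim <- simulate_cohort(cc, seed = 3L)
  pi <- suppressMessages(phagocytic_index(sim$counts))
  expect_true(all(pi$phagocytic_index[!is.na(pi$phagocytic_index)] == 1))
  # zero-count cell types occur in realistic cohorts and are excluded cleanly
  sim2 <- simulate_cohort(cohort_config(n_per_group = 10L), seed = 5L)
  expect_true(any(sim2$counts$n_total == 0L))
  spi <- suppressMessages(specific_phagocytic_index(sim2$counts))
  expect_true(all(is.na(spi$spi) == (spi$n_total == 0L)))
})

test_that("hemocytometer observations reflect the simulated concentrations", {
  cc <- cohort_config(n_per_group = 40L)
  sim <- simulate_cohort(cc, seed = 9L)
  est <- hemocyte_concentration(sim$hemocytometer$cells_counted,
                                sim$hemocytometer$n_squares,
                                sim$hemocytometer$dilution_fraction)
  # per-larva Poisson noise is small at ~700 counted cells
  expect_lt(median(abs(est - sim$hemocytometer$thc_true) /
                     sim$hemocytometer$thc_true), 0.1)
  expect_lt(abs(mean(est) / cc$thc_mean - 1), 0.25)
})
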