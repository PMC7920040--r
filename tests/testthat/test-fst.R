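test_that("biallelic reduction picks alleles by summed counts with fixed ties", {
  # A/T tie broken toward A as major; minor frequencies 0 and 1
  s <- call_snps(site1(c(10, 0, 0, 0, 0, 0), c(0, 10, 0, 0, 0, 0)))
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$major, s$minor), c("A", "T"))
  expect_equal(c(s$p1, s$p2), c(0, 1))
  expect_equal(s$fst, 1)

  # identical pools are rejected as monomorphic, a tagged outcome
  r <- call_snps(site1(c(10, 0, 0, 0, 0, 0), c(10, 0, 0, 0, 0, 0)))
  expect_equal(nrow(r), 0L)
  expect_equal(unname(attr(r, "rejections")["monomorphic"]), 1L)

  # minor allele by summed counts: A (8) is minor vs T (12)
  x <- call_snps(site1(c(6, 4, 0, 0, 0, 0), c(2, 8, 0, 0, 0, 0)))
  expect_equal(c(x$major, x$minor), c("T", "A"))
  expect_equal(c(x$p1, x$p2), c(0.6, 0.2))
  expect_equal(x$fst, 1 / 6, tolerance = 1e-12)
})

test_that("coverage and minor-count thresholds reject accordingly", {
  filt <- snp_filter(min_minor_count = 2L, min_coverage = 10L,
                     max_coverage = 20L)
  low <- call_snps(site1(c(5, 4, 0, 0, 0, 0), c(6, 6, 0, 0, 0, 0)), filt)
  expect_equal(nrow(low), 0L)
  expect_equal(unname(attr(low, "rejections")["low_coverage"]), 1L)
  high <- call_snps(site1(c(30, 4, 0, 0, 0, 0), c(6, 6, 0, 0, 0, 0)), filt)
  expect_equal(unname(attr(high, "rejections")["high_coverage"]), 1L)
  singleton <- call_snps(site1(c(10, 1, 0, 0, 0, 0), c(10, 0, 0, 0, 0, 0)), filt)
  expect_equal(unname(attr(singleton, "rejections")["low_minor_count"]), 1L)
  # N and deletions are never alleles and do not contribute to coverage
  ndel <- call_snps(site1(c(6, 4, 0, 0, 9, 9), c(6, 6, 0, 0, 9, 9)), filt)
  expect_equal(nrow(ndel), 1L)
  expect_equal(ndel$n1_major + ndel$n1_minor, 10L)
})

test_that("snp-level FST matches the hand-computed examples", {
  ex <- fst_nei(0.4, 0.8)
  expect_equal(ex$h_within, 0.40, tolerance = 1e-12)
  expect_equal(ex$h_total, 0.48, tolerance = 1e-12)
  expect_equal(ex$fst, 1 / 6, tolerance = 1e-12)
  expect_equal(fst_nei(0.3, 0.3)$fst, 0)
  expect_equal(fst_nei(0, 1)$fst, 1)
})

test_that("snp FST equals an independent brute-force oracle on random inputs", {
  withr::with_seed(101L, {
    n1 <- 5L + rpois(1000L, 40)
    n2 <- 5L + rpois(1000L, 40)
    k1 <- rbinom(1000L, n1, runif(1000L, 0.02, 0.98))
    k2 <- rbinom(1000L, n2, runif(1000L, 0.02, 0.98))
  })
  keep <- (k1 + k2) > 0L & (k1 + k2) < (n1 + n2) # polymorphic only
  p1 <- k1[keep] / n1[keep]
  p2 <- k2[keep] / n2[keep]
  expect_equal(fst_nei(p1, p2)$fst, oracle_fst(p1, p2), tolerance = 1e-12)
})

test_that("snp FST is symmetric under pool exchange and allele relabeling", {
  withr::with_seed(7L, { p1 <- runif(200L, 0.01, 0.99); p2 <- runif(200L, 0.01, 0.99) })
  f <- fst_nei(p1, p2)$fst
  expect_equal(fst_nei(p2, p1)$fst, f, tolerance = 1e-12)
  expect_equal(fst_nei(1 - p1, 1 - p2)$fst, f, tolerance = 1e-12)
})

test_that("FST grows as one population moves away from the other", {
  p2 <- seq(0.5, 0.99, by = 0.01)
  up <- fst_nei(rep(0.5, length(p2)), p2)$fst
  expect_true(all(diff(up) > 0))
  down <- fst_nei(rep(0.5, length(p2)), 1 - p2)$fst
  expect_equal(down, up, tolerance = 1e-12)
})

test_that("the pool correction can go negative but never exceeds 1", {
  withr::with_seed(21L, {
    p1 <- runif(500L, 0.02, 0.98); p2 <- runif(500L, 0.02, 0.98)
    n1 <- 10L + rpois(500L, 60); n2 <- 10L + rpois(500L, 60)
  })
  corr <- fst_nei(p1, p2, n1, n2, correction = "pool", pool_size = 50L)$fst
  expect_true(all(corr <= 1))
  expect_true(any(corr < 0)) # retained, not clamped
  expect_true(all(fst_nei(p1, p2)$fst >= 0))
})

test_that("region FST aggregates by ratio of sums", {
  one <- call_snps(site1(c(6, 4, 0, 0, 0, 0), c(2, 8, 0, 0, 0, 0)))
  expect_equal(region_fst(one), one$fst)
  # (Ht, Hw) pairs (0.48, 0.40) and (0.50, 0.50): (0.98 - 0.90) / 0.98
  two <- rbind(one, call_snps(site1(c(5, 5, 0, 0, 0, 0), c(5, 5, 0, 0, 0, 0),
                                    position = 43L)))
  expect_equal(two$h_total, c(0.48, 0.50), tolerance = 1e-12)
  expect_equal(region_fst(two), 0.08 / 0.98, tolerance = 1e-12)
  # fully differentiated region
  fixed <- call_snps(sync_sites(c("s", "s"), 1:2, c("A", "A"),
                                matrix(c(10L, 0L, 0L, 0L, 0L, 0L), 2, 6, byrow = TRUE),
                                matrix(c(0L, 10L, 0L, 0L, 0L, 0L), 2, 6, byrow = TRUE)))
  expect_equal(region_fst(fixed), 1)
  # empty region is undefined, never zero
  expect_true(is.na(region_fst(one[0, ])))
  # mean-of-SNPs alternative
  expect_equal(region_fst(two, method = "mean"), mean(two$fst))
})

test_that("gene FST separates exonic and flanking-combined aggregation", {
  genes <- gene_models("g1", "scaf1", "+", 100L, 200L)
  # SNPs: one upstream flank (pos 51), one exonic (150), one downstream (250),
  # one far outside (5000)
  mk <- function(pos) site1(c(6, 4, 0, 0, 0, 0), c(2, 8, 0, 0, 0, 0),
                            position = pos)
  snps <- call_snps(dplyr::bind_rows(mk(51L), mk(150L), mk(250L), mk(5000L)))
  gf <- gene_fst(genes, snps, flank = 100L,
                 scaffold_lengths = c(scaf1 = 10000))
  expect_equal(gf$n_snps, 1L)
  expect_equal(gf$fst_gene, 1 / 6, tolerance = 1e-12)
  expect_equal(gf$n_snps_flanking, 3L) # flanks [0,100) and [200,300)
  expect_equal(gf$fst_flanking_combined,
               oracle_region_fst(c(0.6, 0.6, 0.6), c(0.2, 0.2, 0.2)),
               tolerance = 1e-12)
  # no SNPs in flanks: combined equals exonic
  gf2 <- gene_fst(genes, call_snps(mk(150L)), flank = 100L,
                  scaffold_lengths = c(scaf1 = 10000))
  expect_equal(gf2$fst_flanking_combined, gf2$fst_gene)
})

test_that("flanks clip at scaffold boundaries", {
  genes <- gene_models("g1", "scaf1", "+", 50L, 150L)
  mk <- function(pos) site1(c(6, 4, 0, 0, 0, 0), c(2, 8, 0, 0, 0, 0),
                            position = pos)
  # upstream flank would be [-4950, 50): clipped to [0, 50); a SNP at 1-based
  # 10 is inside, the downstream flank clips at the 200 bp scaffold
  snps <- call_snps(dplyr::bind_rows(mk(10L), mk(100L), mk(190L)))
  gf <- gene_fst(genes, snps, flank = 5000L, scaffold_lengths = c(scaf1 = 200))
  expect_equal(gf$n_snps_flanking, 3L)
  expect_equal(gf$n_snps, 1L)
})

test_that("genes without exonic SNPs are undefined and excluded from summaries", {
  genes <- tiny_genes()
  snps <- call_snps(site1(c(6, 4, 0, 0, 0, 0), c(2, 8, 0, 0, 0, 0),
                          position = 150L))
  expect_message(gf <- gene_fst(genes, snps, flank = 10L,
                                scaffold_lengths = c(scaf1 = 2000)),
                 "without exonic SNPs")
  expect_true(is.na(gf$fst_gene[gf$gene_id == "g2"]))
  summ <- genomewide_summary(snps, gf)
  expect_equal(summ$value[summ$metric == "n_genes_with_fst"], 1)
  expect_equal(summ$value[summ$metric == "mean_gene_fst"],
               mean(gf$fst_gene, na.rm = TRUE))
  expect_equal(summ$value[summ$metric == "mean_snp_fst"], mean(snps$fst))
  # empty input: zero counts, undefined means
  e <- genomewide_summary(snps[0, ])
  expect_equal(e$value[e$metric == "n_snps"], 0)
  expect_true(is.na(e$value[e$metric == "mean_snp_fst"]))
})
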