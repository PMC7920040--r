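test_that("sync lines parse field-by-field and empty files give empty tables", {
  f <- withr::local_tempfile(fileext = ".sync")
  writeLines("scaf1\t42\tA\t10:0:0:0:0:0\t0:10:0:0:0:0", f)
  s <- read_sync(f)
  expect_equal(nrow(s), 1L)
  expect_equal(s$scaffold, "scaf1")
  expect_equal(s$position, 42L)
  expect_equal(s$ref, "A")
  expect_equal(unlist(s[1, c("A1", "T1", "C1", "G1", "N1", "del1")],
                      use.names = FALSE), c(10L, 0L, 0L, 0L, 0L, 0L))
  expect_equal(unlist(s[1, c("A2", "T2", "C2", "G2", "N2", "del2")],
                      use.names = FALSE), c(0L, 10L, 0L, 0L, 0L, 0L))

  empty <- withr::local_tempfile(fileext = ".sync")
  file.create(empty)
  expect_equal(nrow(read_sync(empty)), 0L)
})

test_that("malformed sync input fails with the offending line number", {
  f <- withr::local_tempfile(fileext = ".sync")
  writeLines(c("scaf1\t1\tA\t1:0:0:0:0:0\t2:0:0:0:0:0",
               "scaf1\t2\tA\t1:0:0:0\t2:0:0:0:0:0"), f)
  expect_error(read_sync(f), "line 2.*six")
  writeLines(c("scaf1\tX\tA\t1:0:0:0:0:0\t2:0:0:0:0:0"), f)
  expect_error(read_sync(f), "line 1.*position")
  writeLines(c("scaf1\t5\tA\t1:0:0:0:0:z\t2:0:0:0:0:0"), f)
  expect_error(read_sync(f), "line 1.*count")
})

test_that("sync write/read round-trips bit-exactly for simulated sites", {
  s <- random_sync(1000L, seed = 11L)
  f <- withr::local_tempfile(fileext = ".sync")
  write_sync(s, f)
  expect_equal(read_sync(f), s)
  # serialisation itself is deterministic: writing twice gives equal bytes
  f2 <- withr::local_tempfile(fileext = ".sync")
  write_sync(s, f2)
  expect_identical(readLines(f), readLines(f2))
  # zero counts serialise in the fixed six-field form
  z <- site1(c(0, 0, 0, 0, 0, 0), c(1, 0, 0, 0, 0, 0))
  fz <- withr::local_tempfile()
  write_sync(z, fz)
  expect_match(readLines(fz), "0:0:0:0:0:0\t1:0:0:0:0:0")
})

test_that("GFF3 coordinates convert to 0-based half-open and back", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "scaf1\t.\tgene\t101\t200\t.\t+\t.\tID=gA",
               "scaf1\t.\texon\t101\t200\t.\t+\t.\tParent=gA"), f)
  g <- read_gene_models(f, "gff3")
  expect_equal(g$start, 100L)
  expect_equal(g$end, 200L)
  # gff_start = internal_start + 1, gff_end = internal_end
  expect_equal(g$start + 1L, 101L)
  expect_equal(g$end, 200L)
})

test_that("BED12 blocks expand with chromStart arithmetic", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("scaf1\t100\t350\tgB\t0\t+\t100\t350\t0\t2\t50,50\t0,100", f)
  g <- read_gene_models(f, "bed12")
  expect_equal(g$start, c(100L, 200L))
  expect_equal(g$end, c(150L, 250L))
  expect_equal(unique(g$gene_id), "gB")
})

test_that("a simulated 500-gene annotation round-trips through GFF3", {
  ann <- simulate_annotation(sim_config(n_genes = 500L), seed = 3L)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(ann$genes, f)
  back <- read_gene_models(f, "gff3")
  expect_equal(back, ann$genes)
})

test_that("GFF3 validation rejects exons outside the gene span", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "scaf1\t.\tgene\t101\t200\t.\t+\t.\tID=gA",
               "scaf1\t.\texon\t150\t250\t.\t+\t.\tParent=gA"), f)
  expect_error(read_gene_models(f, "gff3"), "outside")
})

test_that("indel windows are centred, merged and clipped", {
  # window 5 around 1-based 100 masks 1-based 98..102 = 0-based [97, 102)
  m <- build_indel_mask(tibble::tibble(scaffold = "s", position = 100L), 5L)
  expect_equal(m$start, 97L)
  expect_equal(m$end, 102L)
  # adjacent windows merge
  m2 <- build_indel_mask(tibble::tibble(scaffold = "s",
                                        position = c(100L, 103L)), 5L)
  expect_equal(nrow(m2), 1L)
  expect_equal(c(m2$start, m2$end), c(97L, 105L))
  # clipped at the scaffold start
  m3 <- build_indel_mask(tibble::tibble(scaffold = "s", position = 1L), 5L)
  expect_equal(c(m3$start, m3$end), c(0L, 3L))
  expect_error(build_indel_mask(tibble::tibble(scaffold = "s", position = 1L), 4L),
               "odd")
})

test_that("masking removes masked and non-genic sites and is idempotent", {
  s <- sync_sites(rep("scaf1", 4L), c(99L, 150L, 500L, 1200L), rep("A", 4L),
                  matrix(5L, 4L, 6L), matrix(5L, 4L, 6L))
  mask <- build_indel_mask(tibble::tibble(scaffold = "scaf1", position = 100L))
  out <- apply_masks(s, mask)
  expect_equal(out$position, c(150L, 500L, 1200L)) # 99 is inside [97,102)
  genic <- apply_masks(s, mask, genes = tiny_genes(), genic_only = TRUE)
  expect_equal(genic$position, c(150L, 1200L)) # exonic sites only
  expect_equal(apply_masks(genic, mask, genes = tiny_genes(), genic_only = TRUE),
               genic)
  # genic_only with no genes removes everything
  expect_equal(nrow(apply_masks(s, genes = NULL, genic_only = TRUE)), 0L)
})

test_that("the exonic survival fraction matches the exonic genome fraction", {
  cfg <- sim_config(snp_density = 0.002, monomorphic_density = 0.002)
  ann <- simulate_annotation(cfg, seed = 5L)
  div <- simulate_divergence(cfg, ann, seed = 6L)
  kept <- apply_masks(div$sites, genes = ann$genes, genic_only = TRUE)
  exonic_bp <- sum(ann$genes$end - ann$genes$start)
  genome_bp <- sum(ann$scaffold_lengths)
  frac <- nrow(kept) / nrow(div$sites)
  expect_lt(abs(frac - exonic_bp / genome_bp), 0.005)
})

test_that("annotation maps apply the minimum-term-size filter", {
  map <- annotation_map(list(small = paste0("g", 1:4),
                             big = paste0("g", 1:10),
                             absent = paste0("x", 1:6)))
  bg <- paste0("g", 1:10)
  suppressMessages({
    f5 <- filter_annotation_map(map, bg, min_term_size = 5L)
    f1 <- filter_annotation_map(map, bg, min_term_size = 1L)
  })
  expect_named(f5, "big")             # 4 < 5 dropped; zero-background dropped
  expect_setequal(names(f1), c("small", "big"))
  # a candidate list injected as a term has exactly its in-background size
  cand <- c("g1", "g2", "g9", "not_in_background")
  withc <- add_candidate_term(map, cand, "custom:cand")
  suppressMessages(fc <- filter_annotation_map(withc, bg, min_term_size = 1L))
  expect_length(fc[["custom:cand"]], 3L)
})

test_that("annotation TSV reading keeps labels and pairs", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tterm_id\tterm_label",
               "g1\tT1\talpha", "g2\tT1\talpha", "g3\tT2\tbeta"), f)
  map <- read_annotation_map(f)
  expect_setequal(map[["T1"]], c("g1", "g2"))
  expect_equal(unname(attr(map, "labels")["T2"]), "beta")
  # round trip through the writer
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_map(map, f2)
  expect_equal(read_annotation_map(f2), map)
})
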