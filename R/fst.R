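#' SNP calling thresholds for two-pool data
#'
#' @param min_minor_count minimum minor-allele read count summed across both
#'   pools (default 2).
#' @param min_coverage,max_coverage per-pool coverage bounds over the two
#'   retained alleles (defaults 10 and 500).
#' @return a `snp_filter` list.
#' @export
snp_filter <- function(min_minor_count = 2L, min_coverage = 10L, max_coverage = 500L) {
  assert_that(min_coverage >= 1L, "min_coverage must be >= 1")
  assert_that(max_coverage >= min_coverage, "max_coverage must be >= min_coverage")
  assert_that(min_minor_count >= 1L, "min_minor_count must be >= 1")
  structure(list(min_minor_count = as.integer(min_minor_count),
                 min_coverage = as.integer(min_coverage),
                 max_coverage = as.integer(max_coverage)),
            class = "snp_filter")
}

#' Nei-style two-population fixation index from pool allele frequencies
#'
#' The classical heterozygosity-ratio estimator. Per population
#' `H_i = 1 - p_i^2 - (1 - p_i)^2 = 2 p_i (1 - p_i)`; within-population
#' diversity is the unweighted average `H_w = (H_1 + H_2) / 2`; total
#' diversity uses the unweighted mean frequency `p_bar = (p_1 + p_2) / 2`,
#' `H_t = 2 p_bar (1 - p_bar)`; and `FST = (H_t - H_w) / H_t`. With
#' `correction = "pool"` each `H_i` is multiplied by the finite-sample
#' factor `n_i / (n_i - 1)` where `n_i = min(coverage_i, 2 * pool_size_i)`,
#' after which FST may be negative (negative values are retained, not
#' clamped, to avoid biasing genome-wide means and permutation nulls).
#'
#' @param p1,p2 minor-allele frequencies in the two pools.
#' @param n1,n2 per-pool coverages over the two alleles (needed for the
#'   correction only).
#' @param correction `"none"` (default) or `"pool"`.
#' @param pool_size individuals per pool: scalar or length-2 vector
#'   (required when `correction = "pool"`).
#' @return tibble with columns `h_within`, `h_total`, `fst`.
#' @export
fst_nei <- function(p1, p2, n1 = NULL, n2 = NULL,
                    correction = c("none", "pool"), pool_size = NULL) {
  correction <- match.arg(correction)
  h1 <- 2 * p1 * (1 - p1)
  h2 <- 2 * p2 * (1 - p2)
  if (correction == "pool") {
    assert_that(!is.null(n1) && !is.null(n2) && !is.null(pool_size),
                "the pool correction needs coverages n1, n2 and pool_size")
    pool_size <- rep_len(pool_size, 2L)
    nn1 <- pmin(n1, 2 * pool_size[1L])
    nn2 <- pmin(n2, 2 * pool_size[2L])
    assert_that(all(nn1 > 1) && all(nn2 > 1),
                "corrected estimator needs n > 1 in both pools")
    h1 <- h1 * nn1 / (nn1 - 1)
    h2 <- h2 * nn2 / (nn2 - 1)
  }
  h_within <- (h1 + h2) / 2
  p_bar <- (p1 + p2) / 2
  h_total <- 2 * p_bar * (1 - p_bar)
  assert_that(all(h_total > 0),
              "h_total = 0: site is monomorphic, which the SNP filter must reject")
  tibble::tibble(h_within = h_within, h_total = h_total,
                 fst = (h_total - h_within) / h_total)
}

#' Call biallelic SNPs from two-pool sync sites
#'
#' For each site the two alleles with the highest summed read count across
#' both pools (A/T/C/G only; N and deletions are never alleles) become the
#' major and minor allele; ties are broken by base order A < C < G < T, the
#' earlier base taking the higher rank. Counts of a third-ranked allele are
#' dropped from coverage, not redistributed. A site is rejected - a tagged
#' outcome, not an error - when it is monomorphic over both pools, when
#' either pool's two-allele coverage falls outside
#' `[min_coverage, max_coverage]`, or when the summed minor count is below
#' `min_minor_count`. Rejection counts are kept in the `rejections`
#' attribute of the result.
#'
#' @param sites sync site tibble.
#' @param filter a [snp_filter()].
#' @param correction,pool_size passed to [fst_nei()].
#' @return a SNP tibble: `scaffold`, `position`, `snp_id`, `major`, `minor`,
#'   `n1_major`, `n1_minor`, `n2_major`, `n2_minor`, `p1`, `p2` (minor-allele
#'   frequencies), `h_within`, `h_total`, `fst`; attribute `rejections` is a
#'   named count vector.
#' @export
call_snps <- function(sites, filter = snp_filter(),
                      correction = c("none", "pool"), pool_size = NULL) {
  correction <- match.arg(correction)
  empty <- tibble::tibble(scaffold = character(), position = integer(),
                          snp_id = character(), major = character(),
                          minor = character(), n1_major = integer(),
                          n1_minor = integer(), n2_major = integer(),
                          n2_minor = integer(), p1 = double(), p2 = double(),
                          h_within = double(), h_total = double(), fst = double())
  if (nrow(sites) == 0L) {
    attr(empty, "rejections") <- c(monomorphic = 0L, low_coverage = 0L,
                                   high_coverage = 0L, low_minor_count = 0L,
                                   multiallelic = 0L)
    return(empty)
  }
  bases <- c("A", "T", "C", "G") # sync column order
  m1 <- as.matrix(sites[paste0(bases, 1L)])
  m2 <- as.matrix(sites[paste0(bases, 2L)])
  s <- m1 + m2
  # rank alleles by summed count, ties by base order A < C < G < T
  bonus <- c(A = 3L, T = 0L, C = 2L, G = 1L)[bases]
  key <- s * 4L + matrix(bonus, nrow(s), 4L, byrow = TRUE)
  i_major <- max.col(key, ties.method = "first")
  key[cbind(seq_len(nrow(key)), i_major)] <- -1L
  i_minor <- max.col(key, ties.method = "first")
  rows <- seq_len(nrow(s))
  n1_major <- m1[cbind(rows, i_major)]; n1_minor <- m1[cbind(rows, i_minor)]
  n2_major <- m2[cbind(rows, i_major)]; n2_minor <- m2[cbind(rows, i_minor)]
  cov1 <- n1_major + n1_minor
  cov2 <- n2_major + n2_minor
  minor_total <- n1_minor + n2_minor
  third <- rowSums(s) - s[cbind(rows, i_major)] - s[cbind(rows, i_minor)]

  mono <- minor_total == 0L
  low <- !mono & (cov1 < filter$min_coverage | cov2 < filter$min_coverage)
  high <- !mono & !low & (cov1 > filter$max_coverage | cov2 > filter$max_coverage)
  lowc <- !mono & !low & !high & minor_total < filter$min_minor_count
  keep <- !(mono | low | high | lowc)
  rej <- c(monomorphic = sum(mono), low_coverage = sum(low),
           high_coverage = sum(high), low_minor_count = sum(lowc),
           multiallelic = sum(third > 0L & keep))

  if (!any(keep)) { attr(empty, "rejections") <- rej; return(empty) }
  p1 <- n1_minor[keep] / cov1[keep]
  p2 <- n2_minor[keep] / cov2[keep]
  comp <- fst_nei(p1, p2, cov1[keep], cov2[keep],
                  correction = correction, pool_size = pool_size)
  out <- tibble::tibble(
    scaffold = sites$scaffold[keep], position = sites$position[keep],
    snp_id = paste0(sites$scaffold[keep], ":", sites$position[keep]),
    major = bases[i_major[keep]], minor = bases[i_minor[keep]],
    n1_major = n1_major[keep], n1_minor = n1_minor[keep],
    n2_major = n2_major[keep], n2_minor = n2_minor[keep],
    p1 = p1, p2 = p2,
    h_within = comp$h_within, h_total = comp$h_total, fst = comp$fst)
  attr(out, "rejections") <- rej
  out
}

#' Multi-SNP FST for a region
#'
#' Default is the ratio-of-sums aggregation
#' `(sum H_t - sum H_w) / sum H_t` over the region's SNPs, the standard
#' region estimate that weights informative sites more; `method = "mean"`
#' returns the arithmetic mean of per-SNP FST instead.
#'
#' @param snps a SNP tibble (rows restricted to the region of interest).
#' @param method `"ratio"` (ratio of sums, default) or `"mean"`.
#' @return a single FST value; `NA` (an undefined-result marker, never zero)
#'   for an empty region.
#' @export
region_fst <- function(snps, method = c("ratio", "mean")) {
  method <- match.arg(method)
  if (nrow(snps) == 0L) return(NA_real_)
  if (method == "ratio") {
    (sum(snps$h_total) - sum(snps$h_within)) / sum(snps$h_total)
  } else {
    mean(snps$fst)
  }
}

# (gene index, snp row index) pairs for SNPs overlapping a set of intervals;
# ivs must carry an integer column `gene_i`. Deduplication uses an integer
# key so it stays fast at genome scale.
interval_snp_pairs <- function(ivs, snps) {
  gs <- list(); ss <- list()
  for (sc in unique(ivs$scaffold)) {
    j <- which(ivs$scaffold == sc)
    i <- which(snps$scaffold == sc)
    if (!length(i) || !length(j)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(ivs$start[j] + 1L, ivs$end[j]),
      IRanges::IRanges(snps$position[i], snps$position[i]))
    gs[[sc]] <- ivs$gene_i[j][S4Vectors::queryHits(hits)]
    ss[[sc]] <- i[S4Vectors::subjectHits(hits)]
  }
  dedupe_pairs(list(gene_i = unlist(gs, use.names = FALSE) %||% integer(),
                    snp = unlist(ss, use.names = FALSE) %||% integer()),
               nrow(snps))
}

n_pairs <- function(pairs) length(pairs$snp)

dedupe_pairs <- function(pairs, n_snps) {
  key <- (pairs$gene_i - 1) * (n_snps + 1) + pairs$snp
  keep <- !duplicated(key)
  list(gene_i = pairs$gene_i[keep], snp = pairs$snp[keep])
}

concat_pairs <- function(a, b) {
  list(gene_i = c(a$gene_i, b$gene_i), snp = c(a$snp, b$snp))
}

# aggregate FST over (gene index, snp) pairs; returns vectors aligned to
# gene indices 1..n_genes (NA where a gene has no SNPs)
aggregate_pairs <- function(pairs, snps, method, n_genes) {
  n <- integer(n_genes)
  fst <- rep(NA_real_, n_genes)
  if (n_pairs(pairs) == 0L) return(list(n = n, fst = fst))
  r <- rowsum(cbind(snps$h_total[pairs$snp], snps$h_within[pairs$snp],
                    snps$fst[pairs$snp]), pairs$gene_i)
  idx <- as.integer(rownames(r))
  n <- as.integer(tabulate(pairs$gene_i, n_genes))
  fst[idx] <- if (method == "ratio") {
    (r[, 1L] - r[, 2L]) / r[, 1L]
  } else {
    r[, 3L] / n[idx]
  }
  list(n = n, fst = fst)
}

#' Gene-level and flanking-region FST
#'
#' For each gene, `fst_gene` aggregates the SNPs inside its exons and
#' `fst_flanking_combined` aggregates the SNPs in exons plus the two
#' flanking windows `[gene_start - flank, gene_start)` and
#' `[gene_end, gene_end + flank)` (the flanking + coding region), clipped
#' to the scaffold. Flank extension is symmetric around the span, so the
#' combined region does not depend on strand. Genes with no surviving
#' exonic SNP get `fst_gene = NA` and are excluded from gene-level
#' summaries and permutation backgrounds.
#'
#' @param genes a gene-model table.
#' @param snps a SNP tibble (typically [call_snps()] output).
#' @param flank flank width in bp (default 5000).
#' @param scaffold_lengths named vector of scaffold lengths in bp, used to
#'   clip downstream flanks; when `NULL`, lengths are taken as the furthest
#'   observed coordinate per scaffold.
#' @param method aggregation passed to [region_fst()].
#' @return tibble with one row per gene: `gene_id`, `scaffold`, `strand`,
#'   `start`, `end`, `n_snps`, `fst_gene`, `n_snps_flanking`,
#'   `fst_flanking_combined`.
#' @export
gene_fst <- function(genes, snps, flank = 5000L, scaffold_lengths = NULL,
                     method = c("ratio", "mean")) {
  method <- match.arg(method)
  sp <- gene_spans(genes)
  if (is.null(scaffold_lengths)) {
    scaffold_lengths <- tapply(c(sp$end, snps$position),
                               c(sp$scaffold, snps$scaffold), max)
  }
  slen <- as.numeric(scaffold_lengths[sp$scaffold])
  assert_that(!anyNA(slen), "scaffold_lengths missing for some gene scaffolds")
  ng <- nrow(sp)
  ex_iv <- tibble::tibble(gene_i = match(genes$gene_id, sp$gene_id),
                          scaffold = genes$scaffold,
                          start = genes$start, end = genes$end)
  ex_pairs <- interval_snp_pairs(ex_iv, snps)
  gi <- seq_len(ng)
  fl <- tibble::tibble(gene_i = c(gi, gi), scaffold = c(sp$scaffold, sp$scaffold),
                       start = c(pmax(0, sp$start - flank), sp$end),
                       end = c(sp$start, pmin(slen, sp$end + flank)))
  fl <- fl[fl$start < fl$end, , drop = FALSE]
  fl_pairs <- interval_snp_pairs(fl, snps)
  comb_pairs <- dedupe_pairs(concat_pairs(ex_pairs, fl_pairs), nrow(snps))

  ex <- aggregate_pairs(ex_pairs, snps, method, ng)
  cb <- aggregate_pairs(comb_pairs, snps, method, ng)
  out <- sp
  out$n_snps <- ex$n
  out$fst_gene <- ex$fst
  out$n_snps_flanking <- cb$n
  out$fst_flanking_combined <- cb$fst
  n0 <- sum(out$n_snps == 0L)
  if (n0 > 0L) {
    message(n0, " gene(s) without exonic SNPs: fst_gene undefined, ",
            "excluded from gene-level summaries")
  }
  out
}

#' Map SNPs to the genes whose exons (and optional flanks) contain them
#'
#' The SNP-level analogue of the candidate gene list: e.g. the SNPs falling
#' in candidate genes form the candidate SNP set for SNP-level permutation.
#'
#' @inheritParams gene_fst
#' @param flank flank width; 0 restricts to exons.
#' @return tibble with columns `snp_id`, `gene_id`, `scaffold`, `position`,
#'   `fst` (one row per SNP-gene incidence).
#' @export
snps_in_genes <- function(genes, snps, flank = 0L, scaffold_lengths = NULL) {
  sp <- gene_spans(genes)
  ex_iv <- tibble::tibble(gene_i = match(genes$gene_id, sp$gene_id),
                          scaffold = genes$scaffold,
                          start = genes$start, end = genes$end)
  pairs <- interval_snp_pairs(ex_iv, snps)
  if (flank > 0L) {
    if (is.null(scaffold_lengths)) {
      scaffold_lengths <- tapply(c(sp$end, snps$position),
                                 c(sp$scaffold, snps$scaffold), max)
    }
    slen <- as.numeric(scaffold_lengths[sp$scaffold])
    gi <- seq_len(nrow(sp))
    fl <- tibble::tibble(gene_i = c(gi, gi),
                         scaffold = c(sp$scaffold, sp$scaffold),
                         start = c(pmax(0, sp$start - flank), sp$end),
                         end = c(sp$start, pmin(slen, sp$end + flank)))
    fl <- fl[fl$start < fl$end, , drop = FALSE]
    pairs <- dedupe_pairs(concat_pairs(pairs, interval_snp_pairs(fl, snps)),
                          nrow(snps))
  }
  tibble::tibble(snp_id = snps$snp_id[pairs$snp],
                 gene_id = sp$gene_id[pairs$gene_i],
                 scaffold = snps$scaffold[pairs$snp],
                 position = snps$position[pairs$snp],
                 fst = snps$fst[pairs$snp])
}

#' Genome-wide FST summary table
#'
#' Counts and location statistics of the SNP-level and gene-level FST
#' distributions, in tidy metric/value form ready for CSV export. Empty
#' inputs give zero counts and `NA` means (undefined, never zero).
#'
#' @param snps a SNP tibble.
#' @param gene_fsts optional [gene_fst()] output.
#' @return tibble with columns `metric`, `value`.
#' @export
genomewide_summary <- function(snps, gene_fsts = NULL) {
  q <- function(x, p) if (length(x)) unname(quantile(x, p, type = 7)) else NA_real_
  m <- function(x) if (length(x)) mean(x) else NA_real_
  md <- function(x) if (length(x)) median(x) else NA_real_
  out <- tibble::tibble(
    metric = c("n_snps", "mean_snp_fst", "median_snp_fst", "snp_fst_p975"),
    value = c(nrow(snps), m(snps$fst), md(snps$fst), q(snps$fst, 0.975)))
  if (!is.null(gene_fsts)) {
    gv <- gene_fsts$fst_gene[!is.na(gene_fsts$fst_gene)]
    fv <- gene_fsts$fst_flanking_combined[!is.na(gene_fsts$fst_flanking_combined)]
    out <- rbind(out, tibble::tibble(
      metric = c("n_genes", "n_genes_with_fst", "mean_gene_fst",
                 "median_gene_fst", "gene_fst_p975",
                 "mean_flanking_fst", "flanking_fst_p975"),
      value = c(nrow(gene_fsts), length(gv), m(gv), md(gv), q(gv, 0.975),
                m(fv), q(fv, 0.975))))
  }
  out
}
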