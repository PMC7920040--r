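#' Analysis parameters for the full scan
#'
#' @param flank flanking width in bp (default 5000).
#' @param percentile outlier percentile (default 97.5).
#' @param n_perm permutation replicates (default 10000).
#' @param min_term_size minimum genes per enrichment term (default 5).
#' @param min_minor_count,min_coverage,max_coverage SNP filter (see
#'   [snp_filter()]).
#' @param correction,pool_size FST finite-sample correction (see
#'   [fst_nei()]).
#' @param genic_only restrict sites to exons before SNP calling?
#' @param fst_method region aggregation, `"ratio"` or `"mean"`.
#' @return a `scan_params` list.
#' @export
scan_params <- function(flank = 5000L, percentile = 97.5, n_perm = 10000L,
                        min_term_size = 5L, min_minor_count = 2L,
                        min_coverage = 10L, max_coverage = 500L,
                        correction = "none", pool_size = NULL,
                        genic_only = TRUE, fst_method = "ratio") {
  structure(list(flank = as.integer(flank), percentile = percentile,
                 n_perm = as.integer(n_perm),
                 min_term_size = as.integer(min_term_size),
                 min_minor_count = as.integer(min_minor_count),
                 min_coverage = as.integer(min_coverage),
                 max_coverage = as.integer(max_coverage),
                 correction = correction, pool_size = pool_size,
                 genic_only = genic_only, fst_method = fst_method),
            class = "scan_params")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

require_file <- function(path, what) {
  assert_that(!is.null(path) && file.exists(path),
              paste0("missing ", what, " file: ", path %||% "<NULL>"))
  path
}

#' Run the full divergence-scan analysis
#'
#' Chains the stages in the canonical order - indel/non-genic masking, SNP
#' calling and SNP/gene/flanking FST, candidate-set permutation tests (gene
#' and SNP level), percentile outlier selection, term enrichment, the
#' plot-ready scan table, and (optionally) the immune-assay indices - and
#' writes one CSV per stage plus a JSON manifest into `out_dir`. Any stage
#' error aborts with the stage name and the offending input. All randomness
#' derives from the single `seed`, so a rerun with identical inputs and
#' seed reproduces byte-identical outputs.
#'
#' @param sync path to the two-pool sync file.
#' @param genes path to the gene models (GFF3 or BED12 by extension).
#' @param candidates path to the candidate gene list (one id per line).
#' @param out_dir output directory (created if absent).
#' @param indels optional path to an indel-position TSV.
#' @param annotations optional path to a gene/term TSV for enrichment.
#' @param cell_counts optional path to a tidy cell-count CSV.
#' @param scaffold_lengths optional named vector for flank clipping;
#'   defaults to the furthest observed coordinate per scaffold.
#' @param seed master seed (default 1).
#' @param params a [scan_params()].
#' @return invisibly, a list with every stage result plus `manifest`.
#' @export
run_full_analysis <- function(sync, genes, candidates, out_dir,
                              indels = NULL, annotations = NULL,
                              cell_counts = NULL, scaffold_lengths = NULL,
                              seed = 1L, params = scan_params()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(seed, 2L) # gene-level and SNP-level permutations
  counts <- list()
  outp <- function(name) file.path(out_dir, name)

  inputs <- run_stage("input", {
    sites <- read_sync(require_file(sync, "sync"))
    fmt <- if (grepl("\\.bed$", genes, ignore.case = TRUE)) "bed12" else "gff3"
    gm <- read_gene_models(require_file(genes, "gene model"), format = fmt)
    list(sites = sites, genes = gm)
  })
  counts$sites_read <- nrow(inputs$sites)

  masked <- run_stage("mask", {
    mask <- if (!is.null(indels)) {
      build_indel_mask(read_indel_positions(require_file(indels, "indel")))
    } else NULL
    apply_masks(inputs$sites, mask = mask, genes = inputs$genes,
                genic_only = params$genic_only)
  })
  counts$sites_after_mask <- nrow(masked)

  fst <- run_stage("fst", {
    filt <- snp_filter(params$min_minor_count, params$min_coverage,
                       params$max_coverage)
    snps <- call_snps(masked, filt, correction = params$correction,
                      pool_size = params$pool_size)
    gf <- gene_fst(inputs$genes, snps, flank = params$flank,
                   scaffold_lengths = scaffold_lengths,
                   method = params$fst_method)
    summ <- genomewide_summary(snps, gf)
    write.csv(snps, outp("per_snp_fst.csv"), row.names = FALSE)
    write.csv(gf, outp("per_gene_fst.csv"), row.names = FALSE)
    write.csv(summ, outp("summary.csv"), row.names = FALSE)
    list(snps = snps, gene_fsts = gf, summary = summ)
  })
  counts$snps_called <- nrow(fst$snps)
  counts$genes_with_fst <- sum(!is.na(fst$gene_fsts$fst_gene))

  perm <- run_stage("permutation", {
    cand <- readLines(require_file(candidates, "candidate list"))
    cand <- cand[nzchar(cand)]
    gvals <- setNames(fst$gene_fsts$fst_gene, fst$gene_fsts$gene_id)
    gvals <- gvals[!is.na(gvals)]
    pg <- permute_sets(gvals, cand, n_perm = params$n_perm, seed = seeds[1L])
    cand_snps <- snps_in_genes(inputs$genes[inputs$genes$gene_id %in% cand, ,
                                            drop = FALSE], fst$snps)
    svals <- setNames(fst$snps$fst, fst$snps$snp_id)
    ps <- permute_sets(svals, unique(cand_snps$snp_id),
                       n_perm = params$n_perm, seed = seeds[2L])
    tab <- rbind(perm_test_row(pg, "gene"), perm_test_row(ps, "snp"))
    write.csv(tab, outp("permutation.csv"), row.names = FALSE)
    write.csv(data.frame(gene_null_mean = pg$null_means,
                         snp_null_mean = ps$null_means),
              outp("permutation_null_means.csv"), row.names = FALSE)
    list(gene = pg, snp = ps, candidates = cand, table = tab)
  })

  outl <- run_stage("outliers", {
    gvals <- setNames(fst$gene_fsts$fst_gene, fst$gene_fsts$gene_id)
    fvals <- setNames(fst$gene_fsts$fst_flanking_combined,
                      fst$gene_fsts$gene_id)
    svals <- setNames(fst$snps$fst, fst$snps$snp_id)
    res <- list(gene = select_outliers(gvals, params$percentile),
                flanking = select_outliers(fvals, params$percentile),
                snp = select_outliers(svals, params$percentile))
    tab <- dplyr::bind_rows(lapply(names(res), function(lvl) {
      tibble::tibble(level = lvl, id = res[[lvl]]$outlier_ids,
                     threshold = res[[lvl]]$threshold)
    }))
    write.csv(tab, outp("outliers.csv"), row.names = FALSE)
    res
  })
  counts$gene_outliers <- outl$gene$n_outliers
  counts$snp_outliers <- outl$snp$n_outliers

  enr <- if (!is.null(annotations)) run_stage("enrichment", {
    background <- fst$gene_fsts$gene_id[!is.na(fst$gene_fsts$fst_gene)]
    map <- read_annotation_map(require_file(annotations, "annotation"),
                               min_term_size = params$min_term_size,
                               background = background)
    res <- fisher_enrichment(outl$gene$outlier_ids, map, background)
    write.csv(res, outp("enrichment.csv"), row.names = FALSE)
    res
  }) else NULL
  if (!is.null(enr)) counts$terms_tested <- nrow(enr)

  report <- run_stage("report", {
    rep_tab <- scan_report(fst$gene_fsts, outl$flanking$threshold,
                           perm$candidates)
    write.csv(rep_tab, outp("scan_report.csv"), row.names = FALSE)
    rep_tab
  })

  pheno <- if (!is.null(cell_counts)) run_stage("phenotype", {
    rec <- read_cell_counts(require_file(cell_counts, "cell count"))
    ind <- phagocytic_index(rec)
    spi <- specific_phagocytic_index(rec)
    summ <- assay_summary(rec)
    write.csv(ind, outp("phenotype_individual.csv"), row.names = FALSE)
    write.csv(spi, outp("phenotype_specific_index.csv"), row.names = FALSE)
    write.csv(summ, outp("phenotype_summary.csv"), row.names = FALSE)
    list(individual = ind, specific = spi, summary = summ)
  }) else NULL

  manifest <- run_stage("manifest", {
    paths <- Filter(Negate(is.null),
                    list(sync = sync, genes = genes, candidates = candidates,
                         indels = indels, annotations = annotations,
                         cell_counts = cell_counts))
    man <- list(package = "poolscan",
                version = as.character(packageVersion("poolscan")),
                seed = as.integer(seed), stage_seeds = as.integer(seeds),
                params = unclass(params),
                inputs = lapply(paths, function(p)
                  list(path = p, md5 = unname(md5sum(p)))),
                row_counts = counts)
    jsonlite::write_json(man, outp("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    man
  })

  invisible(list(snps = fst$snps, gene_fsts = fst$gene_fsts,
                 summary = fst$summary, permutation = perm, outliers = outl,
                 enrichment = enr, scan = report, phenotype = pheno,
                 manifest = manifest, out_dir = out_dir))
}
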