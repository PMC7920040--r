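#' Select outliers above a genome-wide empirical percentile
#'
#' The threshold is the linearly interpolated empirical percentile (the
#' common type-7 definition); outliers are the items with value strictly
#' greater than the threshold (the peaks above the line), so ties at the
#' threshold are excluded and counted. Selecting the top 2.5 percent
#' corresponds to the default `percentile = 97.5`.
#'
#' @param values named numeric vector (e.g. per-gene or per-SNP FST); must
#'   be finite. `NA`s are dropped with a message.
#' @param percentile percentile in `[0, 100)` (default 97.5).
#' @return an `outlier_set` list: `threshold`, `outlier_ids`, `n_outliers`,
#'   `n_ties_at_threshold`, `percentile`, `n_values`.
#' @export
select_outliers <- function(values, percentile = 97.5) {
  assert_that(!is.null(names(values)), "values must be named")
  nas <- sum(is.na(values))
  if (nas > 0L) {
    message(nas, " undefined value(s) dropped before outlier selection")
    values <- values[!is.na(values)]
  }
  assert_that(length(values) > 0L, "no values to select outliers from")
  assert_that(all(is.finite(values)), "values must be finite")
  assert_that(percentile >= 0 && percentile < 100, "percentile must be in [0, 100)")
  threshold <- unname(quantile(values, percentile / 100, type = 7, names = FALSE))
  ids <- names(values)[values > threshold]
  ties <- sum(values == threshold)
  if (length(ids) == 0L && stats::var(values) == 0) {
    warning("all values identical: zero outliers", call. = FALSE)
  }
  if (ties > 0L) message(ties, " value(s) tied at the threshold are not outliers")
  structure(list(threshold = threshold, outlier_ids = ids,
                 n_outliers = length(ids), n_ties_at_threshold = ties,
                 percentile = percentile, n_values = length(values)),
            class = "outlier_set")
}

#' @export
print.outlier_set <- function(x, ...) {
  cat(sprintf("%d outlier(s) of %d values above the %.4g%% threshold %.6g\n",
              x$n_outliers, x$n_values, x$percentile, x$threshold))
  invisible(x)
}

#' One-sided hypergeometric (Fisher) term enrichment among outliers
#'
#' Classic Fisher-style over-representation: for each term with `K`
#' background members of which `x` are outliers, among `n` outliers from a
#' background of `N`, the p-value is the hypergeometric upper tail
#' `P(X >= x)`. Benjamini-Hochberg adjustment is applied across the
#' retained terms. The annotation map should already be restricted to the
#' background with the minimum term size applied (see
#' [filter_annotation_map()]).
#'
#' @param outliers character vector of outlier ids (subset of `background`).
#' @param map an `annotation_map`.
#' @param background character vector of background ids (items that could
#'   have been outliers, i.e. with defined values).
#' @return tibble sorted by `p_value`: `term_id`, `term_label`,
#'   `n_outlier_in_term`, `n_term`, `n_outlier`, `n_background`, `p_value`,
#'   `bh_adjusted_p`.
#' @export
fisher_enrichment <- function(outliers, map, background) {
  background <- unique(as.character(background))
  outliers <- unique(as.character(outliers))
  assert_that(length(outliers) > 0L, "empty outlier set")
  assert_that(all(outliers %in% background), "outliers must be a subset of background")
  N <- length(background)
  n <- length(outliers)
  labels <- attr(map, "labels")
  rows <- lapply(names(map), function(t) {
    members <- intersect(map[[t]], background)
    K <- length(members)
    x <- length(intersect(members, outliers))
    tibble::tibble(term_id = t,
                   term_label = labels[[t]] %||% NA_character_,
                   n_outlier_in_term = x, n_term = K, n_outlier = n,
                   n_background = N,
                   p_value = phyper(x - 1, K, N - K, n, lower.tail = FALSE))
  })
  out <- dplyr::bind_rows(rows)
  out$bh_adjusted_p <- p.adjust(out$p_value, method = "BH")
  dplyr::arrange(out, p_value, term_id)
}

#' Plot-ready genome-scan table
#'
#' One row per gene in genomic order with its flanking-combined FST, outlier
#' flag (strictly above the supplied threshold) and candidate flag -
#' sufficient to redraw a per-gene scan with the percentile line and
#' candidate genes highlighted.
#'
#' @param gene_fsts [gene_fst()] output.
#' @param outlier_threshold threshold from [select_outliers()] on the same
#'   value column.
#' @param candidate_ids candidate gene ids.
#' @param value_col which column to scan (default
#'   `"fst_flanking_combined"`).
#' @return tibble: `index`, `gene_id`, `scaffold`, `start`, `value`,
#'   `outlier`, `candidate`.
#' @export
scan_report <- function(gene_fsts, outlier_threshold, candidate_ids,
                        value_col = "fst_flanking_combined") {
  assert_that(value_col %in% names(gene_fsts),
              paste0("no column '", value_col, "' in gene_fsts"))
  d <- dplyr::arrange(gene_fsts, scaffold, start, gene_id)
  v <- d[[value_col]]
  tibble::tibble(index = seq_len(nrow(d)), gene_id = d$gene_id,
                 scaffold = d$scaffold, start = d$start, value = v,
                 outlier = !is.na(v) & v > outlier_threshold,
                 candidate = d$gene_id %in% as.character(candidate_ids))
}
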