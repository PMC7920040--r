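#' Mean of a statistic over a named id set
#'
#' @param values named numeric vector (e.g. per-gene FST, names = gene ids).
#' @param ids ids to average over; every id must be present with a defined
#'   value — callers must drop candidates without data explicitly.
#' @return the arithmetic mean.
#' @export
mean_stat <- function(values, ids) {
  ids <- as.character(ids)
  missing <- setdiff(ids, names(values)[!is.na(values)])
  if (length(missing)) {
    stop("ids without a defined value: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  mean(values[ids])
}

# bitwise-stable mean: summation order independent of sample order, so two
# samples of the same multiset give the identical double
sorted_mean <- function(x) mean(sort(x))

#' Candidate-set permutation test against equally sized random sets
#'
#' Compares the mean statistic of a candidate set with the null distribution
#' of means of `n_perm` sets of the same size drawn uniformly without
#' replacement from the background. The resampling unit is whatever the
#' names of `values` denote - genes (per-gene FST, names = gene ids) or SNPs
#' (per-SNP FST, names = `scaffold:position` ids). By default random sets
#' are drawn from the full background including the candidates (random
#' genome-wide sets, taken literally); `exclude_candidates = TRUE` draws
#' from the complement instead.
#'
#' P-values use the plus-one Monte-Carlo convention
#' `p_greater = (1 + #\{null >= observed\}) / (n_perm + 1)` (ties count in
#' both tails, so p is never 0 and `p_greater + p_less >= 1 + 1/(n_perm+1)`);
#' `p_two_sided = min(1, 2 min(p_greater, p_less))`. All three tails are
#' always reported.
#'
#' @param values named numeric vector of the statistic over the background;
#'   entries with `NA` are dropped with a message.
#' @param candidate_ids candidate ids; silently intersected with the
#'   background (dropped candidates are reported via a message).
#' @param n_perm number of random sets (default 10000).
#' @param seed optional integer; identical seed gives identical results.
#' @param exclude_candidates draw null sets from background minus candidates?
#' @return a `perm_test` object: list with `observed_mean`, `null_means`,
#'   `p_greater`, `p_less`, `p_two_sided`, `n_perm`, `set_size`,
#'   `n_background`, `seed`.
#' @export
permute_sets <- function(values, candidate_ids, n_perm = 10000L, seed = NULL,
                         exclude_candidates = FALSE) {
  assert_that(!is.null(names(values)), "values must be named by resampling unit id")
  nas <- sum(is.na(values))
  if (nas > 0L) {
    message(nas, " background value(s) undefined (NA) and dropped")
    values <- values[!is.na(values)]
  }
  cand <- intersect(unique(as.character(candidate_ids)), names(values))
  dropped <- length(unique(as.character(candidate_ids))) - length(cand)
  if (dropped > 0L) message(dropped, " candidate id(s) not in background, dropped")
  assert_that(length(cand) >= 1L, "no candidate ids present in the background")
  k <- length(cand)
  observed <- sorted_mean(values[cand])
  pool <- if (exclude_candidates) values[!(names(values) %in% cand)] else values
  assert_that(length(pool) >= k, "background smaller than the candidate set")
  null_means <- with_seed_if(seed, {
    vapply(seq_len(n_perm), function(i) sorted_mean(sample(pool, k)), numeric(1))
  })
  p_greater <- (1 + sum(null_means >= observed)) / (n_perm + 1)
  p_less <- (1 + sum(null_means <= observed)) / (n_perm + 1)
  structure(list(observed_mean = observed, null_means = null_means,
                 p_greater = p_greater, p_less = p_less,
                 p_two_sided = min(1, 2 * min(p_greater, p_less)),
                 n_perm = as.integer(n_perm), set_size = k,
                 n_background = length(pool), seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Candidate-set permutation test\n")
  cat(sprintf("  set size %d over background %d; %d permutations\n",
              x$set_size, x$n_background, x$n_perm))
  cat(sprintf("  observed mean = %.6g (null mean %.6g, sd %.3g)\n",
              x$observed_mean, mean(x$null_means), sd(x$null_means)))
  cat(sprintf("  p_greater = %.4g, p_less = %.4g, p_two_sided = %.4g\n",
              x$p_greater, x$p_less, x$p_two_sided))
  invisible(x)
}

#' Tidy one-row summary of a permutation test
#' @param x a `perm_test`.
#' @param unit label for the resampling unit (e.g. `"gene"`, `"snp"`).
#' @return one-row tibble.
#' @export
perm_test_row <- function(x, unit = "gene") {
  tibble::tibble(unit = unit, observed_mean = x$observed_mean,
                 null_mean = mean(x$null_means), null_sd = sd(x$null_means),
                 p_greater = x$p_greater, p_less = x$p_less,
                 p_two_sided = x$p_two_sided, n_perm = x$n_perm,
                 set_size = x$set_size, n_background = x$n_background)
}
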