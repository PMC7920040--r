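CELL_TYPES <- c("granulocyte", "plasmatocyte", "oenocytoid", "other")

#' Hemocyte concentration from a hemocytometer count
#'
#' Neubauer-chamber arithmetic: concentration per microlitre of hemolymph is
#' `(cells_counted * 10) / (n_squares * dilution_fraction)`. The factor 10
#' converts the 0.1 mm chamber depth to a 1 uL column; `dilution_fraction`
#' is the hemolymph fraction of the counted suspension (e.g. `1/20` for
#' 8 uL hemolymph in 160 uL total), *not* the fold-dilution factor.
#' With 700 cells over 10 squares at 1/20 this gives 14,000 cells/uL.
#'
#' @param cells_counted non-negative cell count (vectorised).
#' @param n_squares number of large squares counted, `>= 1`.
#' @param dilution_fraction hemolymph volume / total volume, in `(0, 1]`.
#' @return cells per microlitre of hemolymph.
#' @export
hemocyte_concentration <- function(cells_counted, n_squares, dilution_fraction) {
  assert_that(all(dilution_fraction > 0 & dilution_fraction <= 1),
              "dilution_fraction must be in (0, 1] (hemolymph fraction)")
  assert_that(all(n_squares >= 1), "n_squares must be >= 1")
  assert_that(all(cells_counted >= 0), "cells_counted must be >= 0")
  (cells_counted * 10) / (n_squares * dilution_fraction)
}

# validate a tidy cell-count table and coerce types
validate_cell_counts <- function(records) {
  need <- c("individual_id", "population", "sex", "replicate_id",
            "cell_type", "n_total", "n_phagocytic")
  missing <- setdiff(need, names(records))
  assert_that(length(missing) == 0L,
              paste0("cell-count table lacks column(s): ",
                     paste(missing, collapse = ", ")))
  records$n_total <- as.integer(records$n_total)
  records$n_phagocytic <- as.integer(records$n_phagocytic)
  assert_that(all(records$n_total >= 0L) && all(records$n_phagocytic >= 0L),
              "cell counts must be non-negative")
  assert_that(all(records$n_phagocytic <= records$n_total),
              "phagocytic count exceeds total count in some record")
  tibble::as_tibble(records)
}

#' Read a tidy cell-count CSV
#'
#' Long format has one row per individual x replicate x cell type with
#' columns `individual_id`, `population`, `sex`, `replicate_id`,
#' `cell_type`, `n_total`, `n_phagocytic`. A wide format with per-type
#' column pairs `total_<type>` / `phagocytic_<type>` is also accepted and
#' pivoted to long.
#'
#' @param path CSV path.
#' @return validated long-format tibble.
#' @export
read_cell_counts <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  d <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!("cell_type" %in% names(d)) && any(startsWith(names(d), "total_"))) {
    d <- tidyr::pivot_longer(d,
      cols = dplyr::matches("^(total|phagocytic)_"),
      names_pattern = "^(total|phagocytic)_(.*)$",
      names_to = c(".value", "cell_type"))
    names(d)[names(d) == "total"] <- "n_total"
    names(d)[names(d) == "phagocytic"] <- "n_phagocytic"
  }
  validate_cell_counts(d)
}

# pool replicate slides/images by summing counts per individual and type
pool_replicates <- function(records) {
  dplyr::summarise(
    dplyr::group_by(records, individual_id, population, sex, cell_type),
    n_total = sum(n_total), n_phagocytic = sum(n_phagocytic), .groups = "drop")
}

#' Overall phagocytic index per individual
#'
#' The proportion of all counted hemocytes containing labelled bacteria:
#' replicates are pooled by summing counts before dividing (the pooled-count
#' index, not the mean of per-replicate indices - the two differ when
#' replicates are unbalanced). Individuals with zero counted hemocytes get
#' `NA`.
#'
#' @param records tidy cell-count tibble ([read_cell_counts()]).
#' @param by_replicate if `TRUE`, return per-replicate indices instead of
#'   pooling (for mixed-model use downstream).
#' @return tibble with `individual_id`, `population`, `sex`
#'   (plus `replicate_id` when `by_replicate`), `n_total`, `n_phagocytic`,
#'   `phagocytic_index`.
#' @export
phagocytic_index <- function(records, by_replicate = FALSE) {
  records <- validate_cell_counts(records)
  grp <- if (by_replicate) {
    dplyr::group_by(records, individual_id, population, sex, replicate_id)
  } else {
    dplyr::group_by(records, individual_id, population, sex)
  }
  out <- dplyr::summarise(grp, n_total = sum(n_total),
                          n_phagocytic = sum(n_phagocytic), .groups = "drop")
  out$phagocytic_index <- ifelse(out$n_total > 0, out$n_phagocytic / out$n_total,
                                 NA_real_)
  if (anyNA(out$phagocytic_index)) {
    message(sum(is.na(out$phagocytic_index)),
            " record(s) with zero hemocytes: index undefined")
  }
  out
}

#' Composition of the phagocyte pool by cell type
#'
#' For each individual, the share of each cell type among the phagocytosing
#' cells: `phagocytic_t / sum_t phagocytic_t` (defined only when at least
#' one phagocytosing cell was seen). Shares sum to 1 across types.
#'
#' @param records tidy cell-count tibble.
#' @return tibble with `individual_id`, `population`, `sex`, `cell_type`,
#'   `composition`.
#' @export
phagocyte_composition <- function(records) {
  d <- pool_replicates(validate_cell_counts(records))
  tot <- dplyr::summarise(dplyr::group_by(d, individual_id),
                          total_phag = sum(n_phagocytic), .groups = "drop")
  d <- dplyr::left_join(d, tot, by = "individual_id")
  d$composition <- ifelse(d$total_phag > 0, d$n_phagocytic / d$total_phag, NA_real_)
  d[c("individual_id", "population", "sex", "cell_type", "composition")]
}

#' Specific phagocytic index (per-cell-type propensity)
#'
#' Within one cell type, the proportion of that type engaged in
#' phagocytosis: `phagocytic_t / total_t`. Individuals in which a type was
#' never observed get `NA` for that type and are excluded from that type's
#' analysis (not all slides contain all cell types); exclusions are
#' reported via a message.
#'
#' @param records tidy cell-count tibble.
#' @param cell_types which types to compute (default: all present).
#' @return tibble with `individual_id`, `population`, `sex`, `cell_type`,
#'   `n_total`, `n_phagocytic`, `spi`.
#' @export
specific_phagocytic_index <- function(records, cell_types = NULL) {
  d <- pool_replicates(validate_cell_counts(records))
  if (!is.null(cell_types)) d <- d[d$cell_type %in% cell_types, , drop = FALSE]
  d$spi <- ifelse(d$n_total > 0, d$n_phagocytic / d$n_total, NA_real_)
  if (anyNA(d$spi)) {
    message(sum(is.na(d$spi)), " individual-by-type record(s) with zero cells ",
            "of that type: excluded from that type's analysis")
  }
  d
}

#' Per-group summary of all immune-assay indices
#'
#' Computes the pooled per-individual indices (overall phagocytic index,
#' per-type specific phagocytic index, per-type phagocyte composition) and
#' summarises them by population x sex: mean, SD and the number of
#' individuals with a defined value. No hypothesis tests are performed; the
#' tidy individual-level tables are the intended input for any downstream
#' modelling.
#'
#' @param records tidy cell-count tibble.
#' @return tibble with columns `population`, `sex`, `index`, `mean`, `sd`,
#'   `n` (one row per group per index).
#' @export
assay_summary <- function(records) {
  records <- validate_cell_counts(records)
  pi <- phagocytic_index(records)
  spi <- specific_phagocytic_index(records)
  comp <- phagocyte_composition(records)
  long <- dplyr::bind_rows(
    tibble::tibble(individual_id = pi$individual_id, population = pi$population,
                   sex = pi$sex, index = "phagocytic_index",
                   value = pi$phagocytic_index),
    tibble::tibble(individual_id = spi$individual_id, population = spi$population,
                   sex = spi$sex, index = paste0("spi_", spi$cell_type),
                   value = spi$spi),
    tibble::tibble(individual_id = comp$individual_id,
                   population = comp$population, sex = comp$sex,
                   index = paste0("composition_", comp$cell_type),
                   value = comp$composition))
  dplyr::arrange(dplyr::summarise(
    dplyr::group_by(long, population, sex, index),
    mean = if (any(!is.na(value))) mean(value, na.rm = TRUE) else NA_real_,
    sd = if (sum(!is.na(value)) > 1L) sd(value, na.rm = TRUE) else NA_real_,
    n = sum(!is.na(value)), .groups = "drop"), index, population, sex)
}
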