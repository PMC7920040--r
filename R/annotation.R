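#' Build an annotation map (term -> gene set)
#'
#' @param terms named list: term id -> character vector of gene ids.
#' @param labels optional named character vector of term labels.
#' @return an `annotation_map`: a named list of unique gene-id vectors with a
#'   `labels` attribute.
#' @export
annotation_map <- function(terms, labels = NULL) {
  assert_that(is.list(terms) && !is.null(names(terms)) && all(nzchar(names(terms))),
              "terms must be a named list of gene-id vectors")
  terms <- lapply(terms, function(g) sort(unique(as.character(g))))
  lab <- setNames(rep(NA_character_, length(terms)), names(terms))
  if (!is.null(labels)) lab[names(labels)] <- labels
  structure(terms, labels = lab, class = "annotation_map")
}

#' Restrict an annotation map to a gene background and minimum term size
#'
#' Terms are intersected with the background; terms left with fewer than
#' `min_term_size` member genes are dropped (the nodeSize-style filter that
#' removes terms with fewer than five annotated genes at the default).
#' Terms with zero background members are dropped silently apart from a
#' summary message.
#'
#' @param map an `annotation_map`.
#' @param background character vector of background gene ids.
#' @param min_term_size minimum genes per retained term (default 5).
#' @return the filtered `annotation_map`.
#' @export
filter_annotation_map <- function(map, background, min_term_size = 5L) {
  assert_that(min_term_size >= 1L, "min_term_size must be >= 1")
  trimmed <- lapply(unclass(map), intersect, y = as.character(background))
  empty <- sum(lengths(trimmed) == 0L)
  keep <- lengths(trimmed) >= min_term_size
  if (empty > 0L) message(empty, " term(s) had no background genes and were dropped")
  small <- sum(!keep) - empty
  if (small > 0L) {
    message(small, " term(s) below min_term_size = ", min_term_size, " were dropped")
  }
  annotation_map(trimmed[keep], attr(map, "labels")[names(trimmed)[keep]])
}

#' Read a gene-to-term annotation map from TSV
#'
#' One gene/term pair per line: columns `gene_id`, `term_id` and optionally
#' `term_label`. A header row with those names is detected and skipped.
#'
#' @param path input TSV.
#' @param min_term_size minimum term size after restriction to `background`;
#'   only applied when `background` is given.
#' @param background optional gene background to restrict to.
#' @return an `annotation_map`.
#' @export
read_annotation_map <- function(path, min_term_size = 5L, background = NULL) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) && startsWith(lines[1L], "gene_id\t")) lines <- lines[-1L]
  if (length(lines) == 0L) return(annotation_map(setNames(list(), character())))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  assert_that(all(lengths(fields) >= 2L),
              "annotation map needs at least two tab-separated columns")
  gene <- vapply(fields, `[`, "", 1L)
  term <- vapply(fields, `[`, "", 2L)
  lab <- vapply(fields, function(x) if (length(x) >= 3L) x[3L] else NA_character_, "")
  labels <- tapply(lab, term, function(x) x[!is.na(x)][1L])
  map <- annotation_map(split(gene, term), setNames(as.character(labels), names(labels)))
  if (!is.null(background)) map <- filter_annotation_map(map, background, min_term_size)
  map
}

#' Write an annotation map as TSV
#' @param map an `annotation_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_map <- function(map, path) {
  labels <- attr(map, "labels")
  rows <- unlist(lapply(names(map), function(t) {
    paste(map[[t]], t, labels[[t]] %||% NA_character_, sep = "\t")
  }))
  writeLines(c("gene_id\tterm_id\tterm_label", rows), path)
  invisible(path)
}

#' Add a candidate gene list as a custom term
#'
#' Injects the candidate set (for example, curated phagocytosis genes) as
#' its own term so it can be tested for enrichment alongside the ordinary
#' annotation terms.
#'
#' @param map an `annotation_map`.
#' @param gene_ids candidate gene ids.
#' @param term_id id for the injected term.
#' @param label human-readable label.
#' @return the extended `annotation_map`.
#' @export
add_candidate_term <- function(map, gene_ids, term_id = "custom:candidate_set",
                               label = "candidate gene set") {
  terms <- unclass(map)
  terms[[term_id]] <- as.character(gene_ids)
  labels <- attr(map, "labels")
  labels[[term_id]] <- label
  annotation_map(terms, labels)
}
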