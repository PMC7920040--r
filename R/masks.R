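#' Build an indel mask from indel positions
#'
#' Each indel at 1-based position `p` masks a window of `window` bp centred
#' on the indel: the 0-based half-open interval
#' `[p - 1 - floor(window/2), p - 1 + floor(window/2) + 1)`, clipped at the
#' scaffold start. Overlapping windows are merged, so the resulting mask has
#' disjoint intervals per scaffold.
#'
#' @param indels tibble/data.frame with columns `scaffold` and `position`
#'   (1-based), e.g. from [read_indel_positions()].
#' @param window window width in bp; odd, `>= 1`. Default 5.
#' @return a mask table: tibble with columns `scaffold`, `start`, `end`
#'   (0-based half-open, merged).
#' @export
build_indel_mask <- function(indels, window = 5L) {
  window <- as.integer(window)
  assert_that(window >= 1L && window %% 2L == 1L, "window must be odd and >= 1")
  if (nrow(indels) == 0L) {
    return(tibble::tibble(scaffold = character(), start = integer(), end = integer()))
  }
  half <- window %/% 2L
  p0 <- as.integer(indels$position) - 1L
  mask_table(indels$scaffold, pmax(0L, p0 - half), p0 + half + 1L)
}

# merge raw intervals into a canonical disjoint-per-scaffold mask table
mask_table <- function(scaffold, start, end) {
  parts <- lapply(split(seq_along(scaffold), as.character(scaffold)), function(i) {
    ir <- IRanges::reduce(IRanges::IRanges(start[i] + 1L, end[i])) # to 1-based closed
    tibble::tibble(scaffold = as.character(scaffold[i[1L]]),
                   start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  })
  out <- dplyr::bind_rows(parts)
  dplyr::arrange(out, scaffold, start)
}

#' Read indel positions from a two-column TSV
#'
#' Expects tab-separated `scaffold`, `position` (1-based); a header line is
#' detected and skipped if the second field is not an integer.
#'
#' @param path input file.
#' @return tibble with columns `scaffold`, `position`.
#' @export
read_indel_positions <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(tibble::tibble(scaffold = character(), position = integer()))
  }
  f1 <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (is.na(suppressWarnings(as.integer(f1[2L])))) lines <- lines[-1L]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  assert_that(all(lengths(fields) >= 2L), "indel file needs two tab-separated columns")
  m <- vapply(fields, `[`, character(2L), 1:2)
  pos <- suppressWarnings(as.integer(m[2L, ]))
  assert_that(!anyNA(pos), "indel positions must be integers")
  tibble::tibble(scaffold = m[1L, ], position = pos)
}

#' Write indel positions as TSV
#' @param indels tibble with `scaffold`, `position`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_indel_positions <- function(indels, path) {
  writeLines(c("scaffold\tposition",
               paste(indels$scaffold, indels$position, sep = "\t")), path)
  invisible(path)
}

# TRUE for each 1-based position falling inside a 0-based half-open interval set
positions_in_intervals <- function(scaffold, position, ivs) {
  hit <- logical(length(position))
  if (is.null(ivs) || nrow(ivs) == 0L || length(position) == 0L) return(hit)
  for (sc in unique(ivs$scaffold)) {
    i <- which(scaffold == sc)
    if (!length(i)) next
    j <- ivs$scaffold == sc
    ir <- IRanges::IRanges(ivs$start[j] + 1L, ivs$end[j]) # 1-based closed
    q <- IRanges::IRanges(position[i], position[i])
    hit[i] <- IRanges::overlapsAny(q, ir)
  }
  hit
}

#' Filter sync sites by mask and genic context
#'
#' Removes sites that fall inside any mask interval and, when `genic_only`,
#' sites outside every gene. Order is preserved and the operation is
#' idempotent. The genic restriction defaults to exons, mirroring a
#' gene-wise sync built from coding features; `feature = "gene"` keeps any
#' site within a gene span (introns included).
#'
#' @param sites sync site tibble.
#' @param mask a mask table (e.g. [build_indel_mask()]), or `NULL`.
#' @param genes a gene-model table, required when `genic_only = TRUE`.
#' @param genic_only drop sites outside all genes?
#' @param feature `"exon"` (default) or `"gene"`: what counts as genic.
#' @return the filtered sync site tibble.
#' @export
apply_masks <- function(sites, mask = NULL, genes = NULL, genic_only = FALSE,
                        feature = c("exon", "gene")) {
  feature <- match.arg(feature)
  keep <- !positions_in_intervals(sites$scaffold, sites$position, mask)
  if (genic_only) {
    if (is.null(genes) || nrow(genes) == 0L) {
      keep[] <- FALSE
    } else {
      ivs <- if (feature == "exon") genes else gene_spans(genes)
      keep <- keep & positions_in_intervals(sites$scaffold, sites$position,
                                            ivs[c("scaffold", "start", "end")])
    }
  }
  sites[keep, , drop = FALSE]
}
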