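SYNC_BASES <- c("A", "T", "C", "G", "N", "del")
SYNC_COLS <- c(paste0(SYNC_BASES, 1L), paste0(SYNC_BASES, 2L))

#' Construct a table of per-site pooled allele counts
#'
#' The atomic genomic observation: one row per position with the six
#' Popoolation2 allele counts (A, T, C, G, N, deletion) for each of the two
#' pools. Counts are validated to be non-negative integers and positions to
#' be 1-based.
#'
#' @param scaffold character vector of scaffold identifiers.
#' @param position integer vector of 1-based positions.
#' @param ref reference base per site, one of `A`, `C`, `G`, `T`, `N`.
#' @param counts1,counts2 integer matrices with six columns in the order
#'   A, T, C, G, N, deletion: read counts for pool 1 and pool 2.
#' @return a tibble with columns `scaffold`, `position`, `ref` and the twelve
#'   count columns `A1 ... del1, A2 ... del2`.
#' @export
sync_sites <- function(scaffold, position, ref, counts1, counts2) {
  counts1 <- as.matrix(counts1)
  counts2 <- as.matrix(counts2)
  n <- length(scaffold)
  assert_that(length(position) == n && length(ref) == n &&
                nrow(counts1) == n && nrow(counts2) == n,
              "sync fields must have one entry per site")
  assert_that(ncol(counts1) == 6L && ncol(counts2) == 6L,
              "counts must have six columns (A,T,C,G,N,del)")
  position <- as.integer(position)
  assert_that(!anyNA(position) && all(position >= 1L),
              "positions must be integers >= 1")
  assert_that(all(ref %in% c("A", "C", "G", "T", "N")),
              "reference base must be one of A,C,G,T,N")
  cnt <- cbind(counts1, counts2)
  storage.mode(cnt) <- "integer"
  assert_that(!anyNA(cnt) && all(cnt >= 0L), "counts must be non-negative integers")
  colnames(cnt) <- SYNC_COLS
  out <- tibble::tibble(scaffold = as.character(scaffold),
                        position = position, ref = as.character(ref))
  out[SYNC_COLS] <- as.data.frame(cnt)
  out
}

#' Read a Popoolation2 sync file (two pools)
#'
#' Parses the tab-separated sync dialect: scaffold, 1-based position,
#' reference base, then one colon-separated `A:T:C:G:N:del` count field per
#' pool. Exactly two pools are read; extra pool columns are an error so that
#' a mis-specified input fails loudly.
#'
#' @param path path to a sync file.
#' @return a sync site tibble as produced by [sync_sites()]; zero rows for an
#'   empty file.
#' @export
read_sync <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(sync_sites(character(), integer(), character(),
                      matrix(integer(), 0, 6), matrix(integer(), 0, 6)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5L)) {
    stop("sync parse error at line ", lineno[which(nf < 5L)[1L]],
         ": expected at least 5 tab-separated columns", call. = FALSE)
  }
  if (any(nf > 5L)) {
    stop("sync parse error at line ", lineno[which(nf > 5L)[1L]],
         ": more than two pool columns found; poolscan reads two-pool sync files",
         call. = FALSE)
  }
  m <- matrix(unlist(fields, use.names = FALSE), nrow = 5L)
  position <- suppressWarnings(as.integer(m[2L, ]))
  if (anyNA(position)) {
    stop("sync parse error at line ", lineno[which(is.na(position))[1L]],
         ": position is not an integer", call. = FALSE)
  }
  parse_pool <- function(col) {
    parts <- strsplit(col, ":", fixed = TRUE)
    bad <- lengths(parts) != 6L
    if (any(bad)) {
      stop("sync parse error at line ", lineno[which(bad)[1L]],
           ": count field must have six ':'-separated values", call. = FALSE)
    }
    cnt <- suppressWarnings(matrix(as.integer(unlist(parts, use.names = FALSE)),
                                   ncol = 6L, byrow = TRUE))
    if (anyNA(cnt)) {
      stop("sync parse error at line ", lineno[which(rowSums(is.na(cnt)) > 0)[1L]],
           ": non-integer allele count", call. = FALSE)
    }
    cnt
  }
  sync_sites(m[1L, ], position, m[3L, ], parse_pool(m[4L, ]), parse_pool(m[5L, ]))
}

#' Write sync sites to a Popoolation2 sync file
#'
#' Serialises bit-exactly in the dialect [read_sync()] parses, so that
#' `read_sync(write_sync(x, f))` round-trips.
#'
#' @param sites a sync site tibble ([sync_sites()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(sites, path) {
  c1 <- do.call(paste, c(unname(as.list(sites[paste0(SYNC_BASES, 1L)])), sep = ":"))
  c2 <- do.call(paste, c(unname(as.list(sites[paste0(SYNC_BASES, 2L)])), sep = ":"))
  lines <- paste(sites$scaffold, sites$position, sites$ref, c1, c2, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# per-pool coverage = sum of the six count fields
sync_coverage <- function(sites, pool) {
  rowSums(as.matrix(sites[paste0(SYNC_BASES, pool)]))
}
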