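#' Construct a gene-model table
#'
#' One row per exon, coordinates 0-based half-open (the internal convention
#' throughout the package; 1-based inclusive coordinates exist only at the
#' GFF3/sync file boundary). Exons are validated to be non-empty,
#' non-overlapping within a gene, and are returned sorted by scaffold, gene
#' start and exon start.
#'
#' @param gene_id,scaffold character vectors, one entry per exon.
#' @param strand `"+"` or `"-"` per exon (constant within a gene).
#' @param start,end 0-based half-open exon bounds, `start < end`.
#' @return a tibble with columns `gene_id`, `scaffold`, `strand`, `start`,
#'   `end`.
#' @export
gene_models <- function(gene_id, scaffold, strand, start, end) {
  out <- tibble::tibble(gene_id = as.character(gene_id),
                        scaffold = as.character(scaffold),
                        strand = as.character(strand),
                        start = as.integer(start), end = as.integer(end))
  assert_that(nrow(out) > 0L, "gene model table must contain at least one exon")
  assert_that(all(out$strand %in% c("+", "-")),
              "unknown strand symbol; expected '+' or '-'")
  assert_that(all(out$start < out$end), "every exon must satisfy start < end")
  assert_that(all(out$start >= 0L), "exon starts must be >= 0")
  bad_scaf <- tapply(out$scaffold, out$gene_id, function(s) length(unique(s)) > 1L)
  assert_that(!any(bad_scaf), "a gene's exons must share one scaffold")
  # order genes by genomic position, exons by start within gene
  gstart <- tapply(out$start, out$gene_id, min)[out$gene_id]
  out <- out[order(out$scaffold, gstart, out$gene_id, out$start), , drop = FALSE]
  ov <- unlist(tapply(seq_len(nrow(out)), out$gene_id, function(i) {
    s <- out$start[i][order(out$start[i])]
    e <- out$end[i][order(out$start[i])]
    any(s[-1L] < e[-length(e)])
  }))
  assert_that(!any(ov), "overlapping exons within a gene")
  out
}

#' Per-gene spans from a gene-model table
#'
#' @param genes a gene-model table ([gene_models()]).
#' @return tibble with one row per gene: `gene_id`, `scaffold`, `strand`,
#'   `start`, `end` (0-based half-open span from first exon start to last
#'   exon end), ordered by scaffold and start.
#' @export
gene_spans <- function(genes) {
  sp <- dplyr::summarise(dplyr::group_by(genes, gene_id),
                         scaffold = scaffold[1L], strand = strand[1L],
                         start = min(start), end = max(end), .groups = "drop")
  dplyr::arrange(sp, scaffold, start, gene_id)
}

#' Read gene models from GFF3 or BED12
#'
#' GFF3 input uses `gene` features (`ID=`) and their `exon` children
#' (`Parent=`); 1-based inclusive coordinates are converted to the internal
#' 0-based half-open convention (`start - 1`, `end`). A gene without exon
#' children contributes its whole span as a single exon. BED12 blocks are
#' expanded to exon intervals with the usual chromStart + blockStart
#' arithmetic (BED is already 0-based half-open).
#'
#' @param path input file.
#' @param format `"gff3"` or `"bed12"`.
#' @return a gene-model table ([gene_models()]).
#' @export
read_gene_models <- function(path, format = c("gff3", "bed12")) {
  format <- match.arg(format)
  assert_that(file.exists(path), paste0("no such file: ", path))
  if (format == "gff3") {
    d <- rtracklayer::readGFF(path)
    d <- as.data.frame(d)
    gn <- d[d$type == "gene", , drop = FALSE]
    ex <- d[d$type == "exon", , drop = FALSE]
    assert_that(nrow(gn) > 0L, "GFF3 contains no gene features")
    parent <- vapply(ex$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, "")
    assert_that(!anyNA(parent), "GFF3 exon feature without a Parent attribute")
    assert_that(all(parent %in% gn$ID), "GFF3 exon Parent does not match any gene ID")
    span <- gn[match(parent, gn$ID), , drop = FALSE]
    ok <- ex$start >= span$start & ex$end <= span$end &
      as.character(ex$seqid) == as.character(span$seqid)
    assert_that(all(ok), "GFF3 exon lies outside its declared gene span")
    # genes with no exon rows: use the gene span itself
    lone <- gn[!(gn$ID %in% parent), , drop = FALSE]
    gid <- c(parent, lone$ID)
    gene_models(gene_id = gid,
                scaffold = c(as.character(ex$seqid), as.character(lone$seqid)),
                strand = c(as.character(ex$strand),
                           as.character(gn$strand[match(lone$ID, gn$ID)])),
                start = c(ex$start, lone$start) - 1L,
                end = c(ex$end, lone$end))
  } else {
    g <- rtracklayer::import(path, format = "bed")
    assert_that(!is.null(g$name), "BED12 input needs a name column for gene ids")
    blocks <- g$blocks
    if (is.null(blocks)) { # plain BED: one block per record
      blocks <- IRanges::IRangesList(lapply(IRanges::width(g), function(w)
        IRanges::IRanges(1L, w)))
    }
    nb <- lengths(blocks)
    bl <- unlist(blocks)
    off <- rep(GenomicRanges::start(g) - 1L, nb) # 0-based chromStart
    gene_models(gene_id = rep(g$name, nb),
                scaffold = rep(as.character(GenomicRanges::seqnames(g)), nb),
                strand = rep(as.character(GenomicRanges::strand(g)), nb),
                start = off + IRanges::start(bl) - 1L,
                end = off + IRanges::end(bl))
  }
}

#' Write gene models as GFF3
#'
#' Emits one `gene` row per gene and one `exon` row per exon, converting the
#' internal 0-based half-open intervals back to GFF3's 1-based inclusive
#' coordinates. Output ordering is deterministic (scaffold, gene start), so
#' a write/read cycle reproduces the input table exactly.
#'
#' @param genes a gene-model table ([gene_models()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  genes <- gene_models(genes$gene_id, genes$scaffold, genes$strand,
                       genes$start, genes$end)
  sp <- gene_spans(genes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(sp))) {
    g <- sp[i, ]
    writeLines(paste(g$scaffold, "poolscan", "gene", g$start + 1L, g$end, ".",
                     g$strand, ".", paste0("ID=", g$gene_id), sep = "\t"), con)
    ex <- genes[genes$gene_id == g$gene_id, , drop = FALSE]
    writeLines(paste(ex$scaffold, "poolscan", "exon", ex$start + 1L, ex$end, ".",
                     ex$strand, ".", paste0("Parent=", ex$gene_id), sep = "\t"), con)
  }
  invisible(path)
}
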