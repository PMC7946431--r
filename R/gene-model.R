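#' Gene model
#'
#' Strand-aware container for one gene's transcript structures. Exons of every
#' transcript are stored in transcript 5'->3' order: genomic-ascending for
#' plus-strand genes, genomic-descending for minus-strand genes. Exon ordinals
#' (the field's conventional exon numbering, e.g. "exon 17") are kept per
#' transcript when the annotation provides them; otherwise they are assigned
#' by transcript order and flagged provisional.
#'
#' @param gene_id Gene identifier.
#' @param gene_name Gene symbol (may equal `gene_id`).
#' @param contig Contig the gene lies on.
#' @param strand `"+"` or `"-"`.
#' @param transcripts Named list; each element a list with `transcript_id`,
#'   `exons` (data.frame with 0-based half-open `start`, `end`, 5'->3' order),
#'   `cds` (length-2 integer genomic span or `NULL`) and `exon_number`
#'   (integer vector parallel to `exons`, `NA` when unknown).
#' @param ordinals_provisional TRUE when exon numbers were assigned by
#'   position rather than read from the annotation.
#' @return Object of class `"gene_model"`.
#' @export
gene_model <- function(gene_id, gene_name, contig, strand, transcripts,
                       ordinals_provisional = FALSE) {
  stopifnot(strand %in% c("+", "-"))
  for (tx in transcripts) {
    ex <- tx$exons
    stopifnot(is.data.frame(ex), nrow(ex) >= 1L, all(ex$start < ex$end))
    ord <- order(ex$start)
    if (strand == "-") ord <- rev(ord)
    if (!identical(ord, seq_len(nrow(ex)))) {
      stop("exons of transcript ", tx$transcript_id,
           " are not in transcript 5'->3' order")
    }
    gen <- ex[order(ex$start), , drop = FALSE]
    if (nrow(gen) > 1L && any(gen$start[-1L] < gen$end[-nrow(gen)])) {
      stop("overlapping exons in transcript ", tx$transcript_id)
    }
    if (!is.null(tx$cds)) {
      cds <- tx$cds
      covered <- any(gen$start <= cds[1L] & gen$end >= cds[1L] + 1L) &&
        any(gen$start <= cds[2L] - 1L & gen$end >= cds[2L])
      if (!covered) stop("CDS span outside exon union in transcript ",
                         tx$transcript_id)
    }
  }
  structure(list(gene_id = gene_id, gene_name = gene_name, contig = contig,
                 strand = strand, transcripts = transcripts,
                 ordinals_provisional = ordinals_provisional),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$gene_id, " (", x$gene_name, ") ", x$contig, ":",
      x$strand, ", ", length(x$transcripts), " transcript(s)\n", sep = "")
  for (tx in x$transcripts) {
    cat("  ", tx$transcript_id, ": ", nrow(tx$exons), " exons",
        if (!is.null(tx$cds)) sprintf(", CDS [%d,%d)", tx$cds[1], tx$cds[2]),
        "\n", sep = "")
  }
  invisible(x)
}

#' Genomic span of a gene model
#' @param gene A [gene_model()].
#' @return A [gi()] covering all exons.
#' @export
gene_span <- function(gene) {
  ex <- do.call(rbind, lapply(gene$transcripts, `[[`, "exons"))
  gi(gene$contig, min(ex$start), max(ex$end), gene$strand)
}

# All annotated exon intervals, unique, as a genomic-ascending data.frame
annotated_exons <- function(gene) {
  ex <- do.call(rbind, lapply(gene$transcripts, `[[`, "exons"))
  ex <- unique(ex[, c("start", "end")])
  ex[order(ex$start, ex$end), , drop = FALSE]
}

# Annotated splice-site coordinates in the intron-boundary convention used by
# the junction index: for a plus-strand gene a donor coordinate is an exon
# end (== intron start) and an acceptor coordinate an exon start (== intron
# end); on the minus strand the roles flip.
annotated_sites <- function(gene) {
  ex <- annotated_exons(gene)
  if (gene$strand == "+") {
    list(donors = unique(ex$end), acceptors = unique(ex$start))
  } else {
    list(donors = unique(ex$start), acceptors = unique(ex$end))
  }
}

# Annotated introns (gaps between consecutive exons of each transcript),
# unique, genomic coordinates
annotated_introns <- function(gene) {
  out <- list()
  for (tx in gene$transcripts) {
    ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
    if (nrow(ex) < 2L) next
    out[[length(out) + 1L]] <- data.frame(start = ex$end[-nrow(ex)],
                                          end = ex$start[-1L])
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer()))
  res <- unique(do.call(rbind, out))
  res[order(res$start, res$end), , drop = FALSE]
}

# Map a paper-style exon ordinal to its genomic interval (first transcript
# carrying it). Returns NULL when absent.
exon_by_ordinal <- function(gene, ordinal) {
  for (tx in gene$transcripts) {
    hit <- which(tx$exon_number == ordinal)
    if (length(hit)) {
      e <- tx$exons[hit[1L], ]
      return(gi(gene$contig, e$start, e$end, gene$strand))
    }
  }
  NULL
}

# Genomic CDS span of the gene: union over transcripts that declare one
gene_cds_span <- function(gene) {
  spans <- Filter(Negate(is.null), lapply(gene$transcripts, `[[`, "cds"))
  if (!length(spans)) return(NULL)
  m <- do.call(rbind, spans)
  c(min(m[, 1L]), max(m[, 2L]))
}
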