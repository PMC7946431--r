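# Independent oracles and small in-code fixtures shared across the suite.

# reverse complement, written without Biostrings so sequence tests have an
# independent route
revcomp_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1L]]),
        collapse = "")
}

# brute-force codon-by-codon translator (independent loop; Biostrings'
# GENETIC_CODE constant as the code table)
brute_translate <- function(seq, cds_start) {
  gc <- Biostrings::GENETIC_CODE
  i <- cds_start + 1L
  pep <- character()
  stop_at <- NA_integer_
  while (i + 2L <= nchar(seq)) {
    aa <- unname(gc[substr(seq, i, i + 2L)])
    if (is.na(aa)) aa <- "X"
    if (aa == "*") { stop_at <- i - 1L; break }
    pep <- c(pep, aa)
    i <- i + 3L
  }
  list(stop_tx = stop_at, peptide = paste(pep, collapse = ""))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# two-transcript toy GTF (plus strand), written to a temp file
write_toy_gtf <- function(path) {
  at <- function(tx, exn = NULL) {
    s <- sprintf('gene_id "G1"; gene_name "toy";%s',
                 if (is.null(tx)) "" else sprintf(' transcript_id "%s";', tx))
    if (!is.null(exn)) s <- paste0(s, sprintf(' exon_number "%d";', exn))
    s
  }
  lines <- c(
    paste("chr1\tsrc\tgene\t101\t1000\t.\t+\t.", at(NULL), sep = "\t"),
    paste("chr1\tsrc\ttranscript\t101\t1000\t.\t+\t.", at("T1"), sep = "\t"),
    paste("chr1\tsrc\texon\t101\t200\t.\t+\t.", at("T1", 1L), sep = "\t"),
    paste("chr1\tsrc\texon\t301\t400\t.\t+\t.", at("T1", 2L), sep = "\t"),
    paste("chr1\tsrc\texon\t801\t1000\t.\t+\t.", at("T1", 3L), sep = "\t"),
    paste("chr1\tsrc\tCDS\t151\t900\t.\t+\t.", at("T1"), sep = "\t"),
    paste("chr1\tsrc\ttranscript\t101\t1000\t.\t+\t.", at("T2"), sep = "\t"),
    paste("chr1\tsrc\texon\t101\t200\t.\t+\t.", at("T2", 1L), sep = "\t"),
    paste("chr1\tsrc\texon\t801\t1000\t.\t+\t.", at("T2", 2L), sep = "\t"))
  writeLines(lines, path)
  path
}

# junction BED12 line in the regtools dialect
junc_line <- function(contig, chromStart, chromEnd, strand, score, b1, b2,
                      name = "JUNC0001") {
  sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t255,0,0\t2\t%d,%d\t0,%d",
          contig, chromStart, chromEnd, name, score, strand, chromStart,
          chromEnd, b1, b2, chromEnd - chromStart - b2)
}

# hand-built plus-strand gene model: 3 exons at [100,200) [300,400) [800,1000)
toy_gene <- function(strand = "+", ordinals = 1:3) {
  ex <- data.frame(start = c(100L, 300L, 800L), end = c(200L, 400L, 1000L))
  if (strand == "-") ex <- ex[3:1, ]
  gene_model("G1", "toy", "chr1", strand,
             transcripts = list(T1 = list(transcript_id = "T1", exons = ex,
                                          exon_number = ordinals,
                                          cds = c(150L, 900L))))
}

# junction data.frame row in read_junctions_bed layout
jrow <- function(start, end, count, sample_id = "s1", condition = "WT",
                 contig = "chr1", strand = "+") {
  data.frame(contig = contig, start = as.integer(start),
             end = as.integer(end), strand = strand,
             count = as.integer(count), sample_id = sample_id,
             condition = condition, name = "J", anchor1 = 8L, anchor2 = 8L)
}
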