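# Transcript splicing, ORF scanning, NMD classification, protein mass

fa_genome <- function(seq, name = "chr1") {
  p <- tempfile(fileext = ".fa")
  writeLines(c(paste0(">", name), seq), p)
  read_fasta(p)
}

plus_gene <- function(exons, cds = NULL) {
  gene_model("G", "g", "chr1", "+",
             transcripts = list(T1 = list(transcript_id = "T1",
                                          exons = exons,
                                          exon_number = seq_len(nrow(exons)),
                                          cds = cds)))
}

test_that("splice_transcript concatenates exons and records junctions", {
  genome <- fa_genome("AAATTTCCCGGG")
  ex <- data.frame(start = c(0L, 6L), end = c(3L, 9L))
  g <- plus_gene(ex)
  mt <- splice_transcript(g, ex, genome, cds = NULL)
  expect_equal(mt$seq, "AAACCC")
  expect_equal(mt$junctions, 3L)
  # overlapping exons rejected
  bad <- data.frame(start = c(0L, 2L), end = c(3L, 9L))
  expect_error(splice_transcript(g, bad, genome, cds = NULL), "overlap")
  # wrong order for the strand rejected
  expect_error(splice_transcript(g, ex[2:1, ], genome, cds = NULL),
               "transcript 5'->3' order")
})

test_that("minus-strand splicing equals the reverse-complement oracle", {
  set.seed(11)
  s <- random_dna(120L)
  genome <- fa_genome(s)
  ex <- data.frame(start = c(10L, 50L), end = c(30L, 80L))
  gm <- gene_model("G", "g", "chr1", "-",
                   transcripts = list(T1 = list(transcript_id = "T1",
                                                exons = ex[2:1, ],
                                                exon_number = 1:2,
                                                cds = NULL)))
  mt <- splice_transcript(gm, ex[2:1, ], genome, cds = NULL)
  plus_concat <- paste0(substr(s, 11L, 30L), substr(s, 51L, 80L))
  expect_identical(mt$seq, revcomp_chr(plus_concat))
})

test_that("scan_orf finds the first in-frame stop and flags non-stop", {
  genome <- fa_genome("ATGTGA")
  ex <- data.frame(start = 0L, end = 6L)
  mt <- splice_transcript(plus_gene(ex, cds = c(0L, 6L)), ex, genome,
                          cds = c(0L, 6L))
  orf <- scan_orf(mt)
  expect_equal(orf$peptide, "M")
  expect_equal(orf$stop_tx, 3L)
  expect_false(orf$non_stop)

  genome2 <- fa_genome("ATGAAA")
  mt2 <- splice_transcript(plus_gene(ex, cds = c(0L, 6L)), ex, genome2,
                           cds = c(0L, 6L))
  expect_true(scan_orf(mt2)$non_stop)
  expect_error(scan_orf(structure(list(seq = "ATG", cds_start = 10L),
                                  class = "mature_transcript")),
               "beyond")
})

test_that("scan_orf agrees with brute-force and Biostrings oracles", {
  set.seed(99)
  for (i in 1:100) {
    n <- 3L * sample(10:60, 1L)
    s <- random_dna(n)
    mt <- structure(list(seq = s, junctions = integer(), cds_start = 0L,
                         chain = data.frame(start = 0L, end = n),
                         strand = "+", contig = "c"),
                    class = "mature_transcript")
    got <- scan_orf(mt)
    want <- brute_translate(s, 0L)
    expect_identical(got$peptide, want$peptide)
    expect_identical(got$stop_tx, want$stop_tx)
    # Biostrings route (C code) on the full frame
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s),
                                             no.init.codon = TRUE))
    aa_first <- sub("\\*.*$", "", aa)
    expect_identical(got$peptide, aa_first)
  }
})

test_that("NMD boundary: 50 nt exactly is not NMD, 51 nt is", {
  # transcript: exon1 long, exon2 short; stop placed so the gap between the
  # stop codon end and the last junction is exactly d
  mk <- function(d, rule = 50L) {
    # CDS: ATG + 20 filler codons + TAA (stop ends at 66); the junction sits
    # d nt after the stop codon
    stop_end <- 66L
    e1_end <- stop_end + d
    s <- paste0("ATG", strrep("AAA", 20L), "TAA", strrep("C", d),
                strrep("G", 100L))
    genome <- fa_genome(s)
    ex <- data.frame(start = c(0L, e1_end), end = c(e1_end, e1_end + 100L))
    mt <- splice_transcript(plus_gene(ex, cds = c(0L, stop_end)), ex, genome,
                            cds = c(0L, stop_end))
    classify_nmd(scan_orf(mt), mt, rule_distance = rule)
  }
  at50 <- mk(50L)
  expect_equal(at50$distance_to_last_junction, 50L)
  expect_false(at50$nmd_predicted)
  at51 <- mk(51L)
  expect_equal(at51$distance_to_last_junction, 51L)
  expect_true(at51$nmd_predicted)
  # rule distance is a parameter, strict inequality preserved
  expect_false(mk(51L, rule = 51L)$nmd_predicted)
  expect_true(mk(20L, rule = 19L)$nmd_predicted)
})

test_that("NMD monotonicity: moving the stop upstream never rescues", {
  # sweep stop positions from far upstream to the junction
  prev <- NULL
  for (stop_codon in seq(10L, 80L, by = 10L)) {
    # exon1 = 273 nt of CDS with the stop sliding downstream as the loop runs
    s <- paste0("ATG", strrep("AAA", stop_codon - 1L), "TAA",
                strrep("AAA", 90L - stop_codon), strrep("G", 100L))
    genome <- fa_genome(s)
    ex <- data.frame(start = c(0L, 273L), end = c(273L, 373L))
    mt <- splice_transcript(plus_gene(ex, cds = c(0L, 273L)), ex, genome,
                            cds = c(0L, 273L))
    orf <- classify_nmd(scan_orf(mt), mt)
    if (!is.null(prev)) expect_gte(prev, orf$nmd_predicted)
    prev <- orf$nmd_predicted
  }
})

test_that("single-exon transcripts are never NMD substrates", {
  genome <- fa_genome("ATGTGAACGTACGT")
  ex <- data.frame(start = 0L, end = 14L)
  mt <- splice_transcript(plus_gene(ex, cds = c(0L, 6L)), ex, genome,
                          cds = c(0L, 6L))
  expect_message(orf <- classify_nmd(scan_orf(mt), mt), "single-exon")
  expect_false(orf$nmd_predicted)
})

test_that("is_ptc compares against the reference stop in transcript orientation", {
  genome <- fa_genome(paste0("ATG", "TAA", strrep("A", 24L), "TGA",
                             strrep("C", 70L)))
  ex <- data.frame(start = c(0L, 60L), end = c(40L, 100L))
  g <- plus_gene(ex, cds = c(0L, 33L))
  mt <- splice_transcript(g, ex, genome, cds = c(0L, 33L))
  orf <- scan_orf(mt)            # stops at the TAA at nt 3
  upstream_ref <- 30L            # reference stop further downstream
  orf <- classify_nmd(orf, mt, reference_stop_genomic = upstream_ref)
  expect_true(orf$is_ptc)
  orf2 <- classify_nmd(scan_orf(mt), mt, reference_stop_genomic = 3L)
  expect_false(orf2$is_ptc)      # same position: not premature
})

test_that("protein mass: standard average table, additivity, edge cases", {
  expect_equal(protein_mass("G"), 75.07, tolerance = 1e-4)
  expect_equal(protein_mass("GG"), 132.12, tolerance = 1e-3)
  # additivity: mass(AB) = mass(A) + mass(B) - water
  set.seed(5)
  res <- names(crypticsplice:::RESIDUE_MASS_AVG)
  for (i in 1:20) {
    a <- paste(sample(res, 5L, replace = TRUE), collapse = "")
    b <- paste(sample(res, 7L, replace = TRUE), collapse = "")
    expect_equal(protein_mass(paste0(a, b)),
                 protein_mass(a) + protein_mass(b) - 18.01528,
                 tolerance = 1e-9)
  }
  expect_equal(protein_mass("", empty = "water"), 18.01528)
  expect_equal(protein_mass("", empty = "zero"), 0)
  expect_error(protein_mass("GZ"), "unknown residue")
})
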