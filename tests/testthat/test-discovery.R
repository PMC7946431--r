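# Junction indexing, cassette calling and classification, isoform logic,
# spliceform enumeration

test_that("junction index assigns donor/acceptor roles by strand", {
  for (st in c("+", "-")) {
    g <- toy_gene(st)
    jx <- jrow(200L, 300L, 10L, strand = st)
    idx <- build_junction_index(jx, g)
    if (st == "+") {
      expect_equal(idx$donor, 200L)
      expect_equal(idx$acceptor, 300L)
    } else {
      expect_equal(idx$donor, 300L)
      expect_equal(idx$acceptor, 200L)
    }
  }
})

test_that("index aggregates counts and excludes out-of-span junctions", {
  g <- toy_gene("+")
  jx <- rbind(jrow(200L, 300L, 10L), jrow(200L, 300L, 5L),
              jrow(200L, 800L, 7L),
              jrow(2000L, 3000L, 9L),          # outside gene span
              jrow(200L, 300L, 4L, strand = "-"))  # strand mismatch
  expect_message(idx <- build_junction_index(jx, g), "excluded")
  expect_equal(nrow(idx), 2L)
  expect_equal(idx$count[idx$acceptor == 300L], 15L)
  expect_equal(nrow(attr(idx, "excluded")), 2L)
})

test_that("three acceptors competing from one donor are indexed with sums", {
  g <- toy_gene("+")
  jx <- rbind(jrow(200L, 300L, 75L), jrow(200L, 800L, 20L),
              jrow(200L, 850L, 5L))
  idx <- build_junction_index(jx, g)
  expect_equal(sort(idx$acceptor[idx$donor == 200L]), c(300L, 800L, 850L))
  expect_equal(sum(idx$count), 100L)
})

test_that("the planted cassette is recovered exactly on both strands", {
  for (st in c("+", "-")) {
    cfg <- sim_config(seed = 31L, strand = st)
    loc <- simulate_locus(cfg)
    sim <- simulate_junction_counts(cfg, loc)
    idx <- build_junction_index(sim$junctions, loc$gene)
    calls <- call_cassette_exons(idx, loc$genome)
    ce1 <- calls[calls$ce_class == "CE1", ]
    expect_equal(nrow(ce1), 1L)
    expect_equal(ce1$segment_start, loc$truth$cryptic$start)
    expect_equal(ce1$segment_end, loc$truth$cryptic$end)
    expect_true(ce1$canonical)
    expect_identical(ce1$acceptor_site, "AG")
    expect_identical(ce1$donor_site, "GT")
    # call invariants
    expect_true(ce1$segment_start >= ce1$host_start)
    expect_true(ce1$segment_end <= ce1$host_end)
    expect_gte(ce1$entry_count, 1L)
    expect_gte(ce1$exit_count, 1L)
  }
})

test_that("annotated-only junctions give an empty call set", {
  g <- toy_gene("+")
  # genome: just enough sequence for dinucleotide checks
  p <- tempfile(fileext = ".fa")
  set.seed(1); writeLines(c(">chr1", random_dna(1100L)), p)
  genome <- read_fasta(p)
  jx <- rbind(jrow(200L, 300L, 75L), jrow(400L, 800L, 60L))
  idx <- build_junction_index(jx, g)
  expect_equal(nrow(call_cassette_exons(idx, genome)), 0L)
  # zero junctions: empty result, not an error
  idx0 <- build_junction_index(jx[0, ], g)
  expect_equal(nrow(call_cassette_exons(idx0, genome)), 0L)
})

test_that("strand mirror symmetry: calls map onto each other", {
  cfg_p <- sim_config(seed = 17L, strand = "+")
  cfg_m <- sim_config(seed = 17L, strand = "-")
  loc_p <- simulate_locus(cfg_p); loc_m <- simulate_locus(cfg_m)
  L <- length(loc_p$genome[[1]])
  call_p <- call_cassette_exons(
    build_junction_index(simulate_junction_counts(cfg_p, loc_p)$junctions,
                         loc_p$gene), loc_p$genome)
  call_m <- call_cassette_exons(
    build_junction_index(simulate_junction_counts(cfg_m, loc_m)$junctions,
                         loc_m$gene), loc_m$genome)
  p1 <- call_p[call_p$ce_class == "CE1", ]
  m1 <- call_m[call_m$ce_class == "CE1", ]
  expect_equal(m1$segment_start, L - p1$segment_end)
  expect_equal(m1$segment_end, L - p1$segment_start)
  expect_equal(m1$support, p1$support)
})

test_that("threshold monotonicity: infinite support kills CE1, support 1 keeps it", {
  cfg <- sim_config(seed = 23L)
  loc <- simulate_locus(cfg)
  idx <- build_junction_index(simulate_junction_counts(cfg, loc)$junctions,
                              loc$gene)
  hi <- call_cassette_exons(idx, loc$genome, min_major_support = .Machine$integer.max)
  expect_false(any(hi$ce_class == "CE1"))
  lo <- call_cassette_exons(idx, loc$genome, min_major_support = 1L)
  expect_true(any(lo$ce_class == "CE1"))
})

test_that("sub-threshold acceptor-sharing extensions become CE2/CE3", {
  cfg <- sim_config(seed = 3L, emit_minor = TRUE)
  loc <- simulate_locus(cfg)
  idx <- build_junction_index(simulate_junction_counts(cfg, loc)$junctions,
                              loc$gene)
  calls <- call_cassette_exons(idx, loc$genome)
  expect_setequal(calls$ce_class, c("CE1", "CE2", "CE3"))
  ce1 <- calls[calls$ce_class == "CE1", ]
  ce2 <- calls[calls$ce_class == "CE2", ]
  ce3 <- calls[calls$ce_class == "CE3", ]
  # extensions share CE1's acceptor; donors numbered downstream-increasing
  expect_equal(ce2$entry_acceptor, ce1$entry_acceptor)
  expect_equal(ce3$entry_acceptor, ce1$entry_acceptor)
  s <- if (loc$gene$strand == "+") 1 else -1
  expect_gt(s * (ce3$exit_donor - ce2$exit_donor), 0)
})

test_that("isoform classification covers the NF155/NF186/NF140 logic", {
  expect_equal(classify_isoform(list(ex23 = TRUE, ex24 = TRUE,
                                     ex28_30 = FALSE, ex27 = FALSE)),
               "NF155")
  expect_equal(classify_isoform(list(ex23 = FALSE, ex24 = FALSE,
                                     ex28_30 = TRUE)), "NF186")
  expect_equal(classify_isoform(list(ex23 = FALSE, ex24 = FALSE,
                                     ex28_30 = FALSE, ex27 = TRUE)),
               "NF140+ex27")
  expect_equal(classify_isoform(list(ex23 = FALSE, ex24 = FALSE,
                                     ex28_30 = FALSE, ex27 = FALSE)),
               "NF140-ex27")
  expect_equal(classify_isoform(list(ex23 = TRUE, ex24 = TRUE,
                                     ex28_30 = TRUE)), "conflict")
  expect_equal(classify_isoform(list(ex23 = TRUE, ex24 = NA,
                                     ex28_30 = FALSE)), "indeterminate")
  expect_equal(classify_isoform(list(ex23 = FALSE, ex24 = FALSE,
                                     ex28_30 = FALSE)), "NF140")
})

test_that("exon usage flags mirror junction-spanning primer logic", {
  # exons 22..25 at [100,200) [300,400) [500,600) [800,1000)
  ex <- data.frame(start = c(100L, 300L, 500L, 800L),
                   end = c(200L, 400L, 600L, 1000L))
  g <- gene_model("G2", "toy2", "chr1", "+",
                  transcripts = list(T1 = list(transcript_id = "T1",
                                               exons = ex,
                                               exon_number = 22:25,
                                               cds = NULL)))
  # ex22 -> ex23 junction: inclusion evidence for 23
  idx_in <- build_junction_index(rbind(jrow(200L, 300L, 30L),
                                       jrow(400L, 500L, 5L)), g)
  flags <- exon_usage_flags(idx_in, 22:25)
  expect_true(flags[["ex23"]])
  expect_true(flags[["ex22"]])   # junction leaves its donor
  # ex22 -> ex25 junction spans exons 23 and 24: skipping evidence
  idx_skip <- build_junction_index(jrow(200L, 800L, 10L), g)
  flags2 <- exon_usage_flags(idx_skip, 22:25)
  expect_false(flags2[["ex23"]])
  expect_false(flags2[["ex24"]])
  # both kinds of evidence at once -> indeterminate
  idx_both <- build_junction_index(rbind(jrow(200L, 300L, 30L),
                                         jrow(200L, 800L, 10L)), g)
  expect_true(is.na(exon_usage_flags(idx_both, 23L)[["ex23"]]))
})

test_that("spliceform enumeration matches the three-path cassette pattern", {
  cfg <- sim_config(seed = 3L, background_depth = 6L)
  loc <- simulate_locus(cfg)
  idx <- build_junction_index(simulate_junction_counts(cfg, loc)$junctions,
                              loc$gene)
  calls <- call_cassette_exons(idx, loc$genome)
  forms <- enumerate_spliceforms(idx, calls, 17L, 19L)
  expect_setequal(forms$path, c("E17-CE1-E19", "E17-E18-E19", "E17-E19"))
  # conservation: path first-junction support sums to the donor totals
  don <- if (loc$gene$strand == "+") {
    crypticsplice:::exon_by_ordinal(loc$gene, 17L)$end
  } else crypticsplice:::exon_by_ordinal(loc$gene, 17L)$start
  for (cc in c("WT", "cKO")) {
    total <- sum(idx$count[idx$donor == don & idx$condition == cc])
    expect_equal(sum(forms[[cc]]), total)
  }
  # without a cryptic call: the two annotated paths remain
  forms0 <- enumerate_spliceforms(idx, calls[0, ], 17L, 19L)
  expect_setequal(forms0$path, c("E17-E18-E19", "E17-E19"))
})
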