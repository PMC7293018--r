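test_that("motif scanning finds forward and reverse-complement hits", {
  h <- scan_motif(c(s = "AAGGCCTAA"), motif_spec("m", "GGCCT", "forward"))
  expect_equal(h$offset, 2L)
  expect_equal(h$strand, "+")

  # TTAGGCCTT: GGCCT forward at offset 3, its revcomp AGGCC at offset 2
  h2 <- scan_motif(c(s = "TTAGGCCTT"), motif_spec("m", "GGCCT"))
  expect_equal(h2$offset, c(2L, 3L))
  expect_setequal(h2$strand, c("-", "+"))

  expect_equal(nrow(scan_motif(c(s = "AAAAAA"), motif_spec("m", "GGCCT"))), 0L)

  # N in the subject never matches; IUPAC in the pattern expands
  expect_equal(nrow(scan_motif(c(s = "GGNCT"), motif_spec("m", "GGCCT"))), 0L)
  expect_equal(scan_motif(c(s = "AGGCCTA"),
                          motif_spec("m", "GGNCT", "forward"))$offset, 1L)
  expect_error(scan_motif(c(s = "AXGT"), motif_spec("m", "GGCCT")), "letters")
  expect_error(motif_spec("m", "G"), "length")
  expect_error(motif_spec("m", "GZ"), "IUPAC")
})

test_that("scanning agrees with the naive sliding-window oracle", {
  set.seed(17)
  patterns <- c("GGCCT", "AGGCCTAG", "GGNCT", "RYSW")
  for (rep_ in 1:250) {
    s <- random_dna(sample(30:80, 1))
    pat <- sample(patterns, 1)
    ours <- scan_motif(c(x = s), motif_spec("m", pat))
    oracle <- naive_scan(s, pat)
    expect_equal(ours$offset, oracle$offset,
                 info = sprintf("seq=%s pat=%s", s, pat))
    expect_equal(ours$strand, as.character(oracle$strand))
  }
})

test_that("top-peak selection ranks by score then coordinate", {
  pk <- peaks_gr("c1", c(500, 300, 900), score = c(5, 3, 1))
  top <- select_top_peaks(pk, 2)
  expect_equal(top$score, c(5, 3))

  tied <- peaks_gr("c1", c(900, 300, 500), score = 2)
  top2 <- select_top_peaks(tied, 2)
  expect_equal(GenomicRanges::start(top2),
               sort(GenomicRanges::start(tied))[1:2])
  expect_warning(select_top_peaks(pk, 10), "available")
})

test_that("matched random regions are width-exact, contained and seeded", {
  src <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(1000, 5000),
                                                       c(2999, 6999)))
  r <- sample_matched_random_regions(src, 20L, n = 500, seed = 3)
  expect_true(all(IRanges::width(r) == 20))
  ov <- GenomicRanges::findOverlaps(r, src, type = "within")
  expect_equal(length(unique(S4Vectors::queryHits(ov))), 500L)
  r2 <- sample_matched_random_regions(src, 20L, n = 500, seed = 3)
  expect_identical(as.character(r), as.character(r2))

  # width equal to the source width forces offset 0
  rw <- sample_matched_random_regions(src, 2000L, n = 50, seed = 4)
  expect_true(all(GenomicRanges::start(rw) %in% GenomicRanges::start(src)))
  expect_error(sample_matched_random_regions(src, 5000L, n = 5), "at least")
})

test_that("motif coverage is exact on planted and motif-free sequences", {
  seqs <- Biostrings::DNAStringSet(c(a = strrep("AT", 50), b = strrep("TA", 50)))
  reg <- GenomicRanges::GRanges(c("a", "b"), IRanges::IRanges(1, 100))
  cov0 <- motif_coverage(reg, seqs, motif_spec("m", "GGCCT"))
  expect_equal(cov0$fraction, 0)

  pl <- plant_motifs(seqs, reg, "GGCCT", count_per_region = 1L, seed = 5)
  cov1 <- motif_coverage(reg, pl$sequences, motif_spec("m", "GGCCT"))
  expect_equal(cov1$fraction, 1)

  bad <- GenomicRanges::GRanges("a", IRanges::IRanges(50, 500))
  expect_error(motif_coverage(bad, seqs, motif_spec("m", "GGCCT")), "bounds")
  unk <- GenomicRanges::GRanges("zz", IRanges::IRanges(1, 10))
  expect_error(motif_coverage(unk, seqs, motif_spec("m", "GGCCT")), "unknown")
})

test_that("coverage is strand-symmetric under reverse complement", {
  set.seed(23)
  seqs <- Biostrings::DNAStringSet(
    setNames(vapply(1:50, function(i) random_dna(300), character(1)),
             sprintf("s%d", 1:50)))
  reg <- GenomicRanges::GRanges(names(seqs), IRanges::IRanges(1, 300))
  f <- motif_coverage(reg, seqs, motif_spec("m", "AGGCCTAG"))$fraction
  r <- motif_coverage(reg, seqs, motif_spec("m", "CTAGGCCT"))$fraction
  expect_equal(f, r)
})

test_that("summit windows cover planted motifs and respect the flank", {
  seqs <- Biostrings::DNAStringSet(c(s = strrep("A", 400)))
  seqs <- plant_motifs(seqs, GenomicRanges::GRanges("s", IRanges::IRanges(198, 202)),
                       "GGCCT", seed = 1)$sequences
  summ <- data.frame(chrom = "s", pos = 200)
  cov <- chexmix_window_coverage(summ, seqs, motif_spec("m", "GGCCT"))
  expect_equal(cov$fraction, 1)
  far <- data.frame(chrom = "s", pos = 250)
  cov2 <- chexmix_window_coverage(far, seqs, motif_spec("m", "GGCCT"))
  expect_equal(cov2$fraction, 0)
  # flank 0 -> 1 nt windows can never contain a >=2 nt motif
  cov3 <- chexmix_window_coverage(summ, seqs, motif_spec("m", "GGCCT"),
                                  flank = 0L)
  expect_equal(cov3$fraction, 0)
  # boundary windows are truncated and flagged
  edge <- data.frame(chrom = "s", pos = 3)
  cov4 <- chexmix_window_coverage(edge, seqs, motif_spec("m", "GGCCT"))
  expect_equal(attr(cov4, "truncated"), 1L)
})

test_that("nested width curves are monotone and saturate on GC-rich islands", {
  g <- generate_genome(genome_config(n_chroms = 1L, chrom_length = 300000L,
                                     n_genes = 40L, seed = 33L))
  motifs <- list(motif_spec("GGCCT", "GGCCT"),
                 motif_spec("AGGCCTAG", "AGGCCTAG"))
  curve <- width_coverage_curve(g$cgi, g$sequences, motifs,
                                widths = c(20, 200, 2000), n = 400, seed = 34)
  expect_true(all(attr(curve, "monotone")))
  gg <- curve[curve$motif == "GGCCT", ]
  expect_true(all(diff(gg$fraction[order(gg$width_class)]) >= 0))
  expect_gt(gg$fraction[gg$width_class == 2000], 0.99)
  expect_lt(gg$fraction[gg$width_class == 20], 0.3)
})
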