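test_that("generators are byte-identical under a repeated seed", {
  cfg <- genome_config(n_chroms = 1L, chrom_length = 120000L, n_genes = 10L,
                       seed = 11L)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
  expect_identical(as.character(g1$models$transcripts),
                   as.character(g2$models$transcripts))
  expect_identical(as.character(g1$cgi), as.character(g2$cgi))

  sim <- simulate_transcripts(200, seed = 5)
  p1 <- generate_peaks(sim$models, peak_mixture_config(), 150,
                       chrom_lengths = sim$chrom_lengths, seed = 9)
  p2 <- generate_peaks(sim$models, peak_mixture_config(), 150,
                       chrom_lengths = sim$chrom_lengths, seed = 9)
  expect_identical(p1$truth, p2$truth)
  expect_identical(p1$track$values, p2$track$values)

  d <- expression_design(seed = 4L)
  e1 <- generate_expression(d, sprintf("g%d", 1:50), c("g1", "g2"), "g10")
  e2 <- generate_expression(d, sprintf("g%d", 1:50), c("g1", "g2"), "g10")
  expect_identical(e1$counts, e2$counts)

  tm <- toy_models()
  m1 <- generate_methylation(tm, n_probes = 100L, n_planted = 5L, seed = 2L)
  m2 <- generate_methylation(tm, n_probes = 100L, n_planted = 5L, seed = 2L)
  expect_identical(m1$probes, m2$probes)
})

test_that("island composition hits the configured GC and CpG enrichment", {
  g <- generate_genome(genome_config(seed = 21L))
  isl <- tssanchor:::extract_region_seqs(g$cgi, g$sequences)
  expect_gt(sum(Biostrings::width(isl)), 10000)
  gc <- sum(Biostrings::letterFrequency(isl, "GC")) /
    sum(Biostrings::width(isl))
  expect_lt(abs(gc - 0.65), 0.015)   # binomial 99% interval at n >= 10 kb
  # CpG dinucleotides enriched relative to background expectation
  cg_isl <- sum(Biostrings::vcountPattern("CG", isl)) /
    sum(Biostrings::width(isl) - 1)
  oe_isl <- cg_isl / (0.325^2)
  expect_gt(oe_isl, 0.6)
  expect_lt(oe_isl, 0.95)
})

test_that("background base composition matches the configured frequencies", {
  cfg <- genome_config(n_chroms = 1L, chrom_length = 120000L, n_genes = 8L,
                       cgi_fraction = 0, seed = 13L)
  g <- generate_genome(cfg)
  expect_equal(length(g$cgi), 0L)
  expect_equal(length(g$cgi_genes), 0L)
  piece <- Biostrings::DNAStringSet(g$sequences[[1]], start = 1, end = 10000)
  obs <- as.numeric(Biostrings::letterFrequency(piece, c("A", "C", "G", "T")))
  p <- c((1 - 0.41) / 2, 0.41 / 2, 0.41 / 2, (1 - 0.41) / 2)
  expect_gt(stats::chisq.test(obs, p = p)$p.value, 0.001)
})

test_that("motif planting round-trips through its manifest", {
  seqs <- Biostrings::DNAStringSet(c(s1 = strrep("A", 200)))
  reg <- GenomicRanges::GRanges("s1", IRanges::IRanges(c(21, 101), c(60, 140)))
  pl <- plant_motifs(seqs, reg, "GGCCT", count_per_region = 2L, seed = 8L)
  expect_equal(nrow(pl$manifest), 4L)
  for (i in seq_len(nrow(pl$manifest))) {
    found <- substr(as.character(pl$sequences[["s1"]]),
                    pl$manifest$start[i], pl$manifest$end[i])
    expect_equal(found, "GGCCT")
  }
  hits <- scan_motif(pl$sequences, motif_spec("m", "GGCCT", "forward"))
  expect_setequal(hits$offset + 1L, pl$manifest$start)

  pl0 <- plant_motifs(seqs, reg, "GGCCT", count_per_region = 0L)
  expect_identical(as.character(pl0$sequences), as.character(seqs))
  tiny <- GenomicRanges::GRanges("s1", IRanges::IRanges(1, 8))
  expect_error(plant_motifs(seqs, tiny, "GGCCTAGGC", count_per_region = 1L),
               "too small")
})

test_that("a degenerate mixture places every summit at the planted offset", {
  sim <- simulate_transcripts(100, seed = 31)
  comp <- data.frame(name = "down_near", weight = 1, mean = 240, sd = 0,
                     score_meanlog = log(10))
  mx <- peak_mixture_config(components = comp)
  gen <- generate_peaks(sim$models, mx, 100, chrom_lengths = sim$chrom_lengths,
                        seed = 32, make_track = FALSE)
  tdf <- tss_of(sim$models)
  m <- match(gen$truth$transcript_id, tdf$transcript_id)
  d <- tss_distance(gen$peaks$summit, tdf$tss[m], tdf$strand[m])
  expect_true(all(d == 240))
})

test_that("mixture component frequencies match their weights", {
  sim <- simulate_transcripts(12000, seed = 41)
  comp <- data.frame(name = c("down_near", "up_near"), weight = c(0.5, 0.5),
                     mean = c(240, -240), sd = c(120, 120),
                     score_meanlog = log(c(10, 10)))
  gen <- generate_peaks(sim$models, peak_mixture_config(components = comp),
                        10000, chrom_lengths = sim$chrom_lengths, seed = 42,
                        make_track = FALSE)
  n_down <- sum(gen$truth$component == "down_near")
  sigma <- sqrt(10000 * 0.25)
  expect_lt(abs(n_down - 5000), 3 * sigma)
})

test_that("null expression designs produce few consensus discoveries", {
  d <- expression_design(direct_down_lfc = 0, indirect_up_lfc = 0, seed = 6L)
  genes <- sprintf("g%04d", 1:2000)
  e <- generate_expression(d, genes, genes[1:100], genes[101:200])
  ctrl <- e$samples$sample[e$samples$condition == "control"]
  degs <- lapply(sprintf("DKO_%d", 1:3), function(cl)
    call_degs(e$counts, ctrl, e$samples$sample[e$samples$condition == cl]))
  cons <- consensus_sets(degs, "down")
  # per-clone FPR is ~alpha at most; three-way intersection should be ~0
  expect_lt(length(cons$all_clones), 5)
})

test_that("noiseless methylation intensities reproduce the planted betas", {
  tm <- toy_models()
  m <- generate_methylation(tm, n_probes = 200L, n_planted = 10L,
                            noise_sd = 0, detect_fail = 0, seed = 14L)
  bm <- probe_beta_matrix(m$probes)
  expect_equal(bm$n_masked, 0L)
  ctrl_cols <- grepl("^control", colnames(bm$beta))
  expect_equal(unname(rowMeans(bm$beta[, ctrl_cols])),
               unname(m$truth$beta_control), tolerance = 2e-3)
  # flagged measurements are exactly the masked ones
  m2 <- generate_methylation(tm, n_probes = 500L, n_planted = 10L,
                             detect_fail = 0.1, seed = 15L)
  bm2 <- probe_beta_matrix(m2$probes)
  pcols <- grep("^p_", names(m2$probes), value = TRUE)
  n_flagged <- sum(vapply(pcols, function(cc) sum(m2$probes[[cc]] > 0.05),
                          integer(1)))
  expect_equal(bm2$n_masked, n_flagged)
})
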