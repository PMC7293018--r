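anchor_df <- function(chrom, tss, strand, id = sprintf("a%d", seq_along(tss)))
  data.frame(peak = id, chrom = chrom, tss = tss, strand = strand,
             stringsAsFactors = FALSE)

test_that("signal matrices orient bins upstream-to-downstream on both strands", {
  # constant coverage -> all-ones matrix
  tr <- binned_track(list(c1 = rep(1, 1000)), 20L)
  m <- build_signal_matrix(tr, anchor_df("c1", 10000, "+"), window = 1000)
  expect_true(all(m$values == 1))
  expect_equal(ncol(m$values), 2 * 1000 / 20 + 1)

  # unit impulse 240 bp downstream -> single nonzero bin at offset +240
  tr2 <- binned_track(list(c1 = rep(0, 1000)), 20L)
  tss <- 10010  # bin-centred so the offset grid aligns
  tr2$values$c1[ceiling((tss + 240) / 20)] <- 1
  mp <- build_signal_matrix(tr2, anchor_df("c1", tss, "+"), window = 3000)
  expect_equal(sum(mp$values != 0), 1L)
  expect_equal(as.numeric(colnames(mp$values)[mp$values != 0]), 240)

  # minus-strand anchor with the impulse 240 bp downstream (5'->3')
  tr3 <- binned_track(list(c1 = rep(0, 1000)), 20L)
  tr3$values$c1[ceiling((tss - 240) / 20)] <- 1
  mm <- build_signal_matrix(tr3, anchor_df("c1", tss, "-"), window = 3000)
  expect_equal(as.numeric(colnames(mm$values)[mm$values != 0]), 240)

  # anchors off-track are dropped with a warning
  expect_warning(
    build_signal_matrix(tr, anchor_df(c("c1", "nope"), c(10000, 5),
                                      c("+", "+")), window = 1000),
    "absent")
})

test_that("profiles recover planted modes, ties broken downstream", {
  offs <- seq(-3000, 3000, 20)
  v <- numeric(length(offs)); names(v) <- offs
  v[offs == 240] <- 5
  p <- tag_density_profile(v, offs)
  expect_equal(p$primary_mode, 240)

  v2 <- numeric(length(offs)); v2[offs == 240] <- 3; v2[offs == -240] <- 3
  p2 <- tag_density_profile(v2, offs)
  expect_equal(p2$primary_mode, 240)   # tie toward positive offsets
  expect_equal(p2$shoulder, -240)

  p0 <- tag_density_profile(numeric(length(offs)), offs)
  expect_true(p0$flagged)
  expect_true(is.na(p0$primary_mode))
})

test_that("the 70/30 near-mode mixture yields a +240 mode and -240 shoulder", {
  comp <- data.frame(name = c("down_near", "up_near"), weight = c(0.7, 0.3),
                     mean = c(240, -240), sd = c(120, 120),
                     score_meanlog = log(c(10, 10)))
  sim <- simulate_transcripts(20000, seed = 51)
  gen <- generate_peaks(sim$models, peak_mixture_config(components = comp),
                        20000, chrom_lengths = sim$chrom_lengths, seed = 52,
                        make_track = FALSE)
  ann <- assign_nearest_tss(gen$peaks, sim$models)
  h <- summit_histogram(ann)
  expect_lte(abs(h$primary_mode - 240), 20)    # within 1 bin
  expect_lte(abs(h$shoulder + 240), 40)        # within 2 bins
})

test_that("the planted +240 mode is recovered within one bin across seeds", {
  comp <- data.frame(name = c("down_near", "up_near"), weight = c(0.7, 0.3),
                     mean = c(240, -240), sd = c(120, 120),
                     score_meanlog = log(c(10, 10)))
  sim <- simulate_transcripts(21000, seed = 61)
  for (sd_ in 1:20) {
    gen <- generate_peaks(sim$models, peak_mixture_config(components = comp),
                          20000, chrom_lengths = sim$chrom_lengths,
                          seed = 600 + sd_, make_track = FALSE)
    ann <- assign_nearest_tss(gen$peaks, sim$models)
    h <- summit_histogram(ann)
    expect_lte(abs(h$primary_mode - 240), 20)
  }
})

test_that("K-means separates impulse groups and is seed-deterministic", {
  offs <- seq(-3000, 3000, 20)
  mk_row <- function(at) { v <- numeric(length(offs)); v[offs == at] <- 1; v }
  vals <- rbind(t(replicate(30, mk_row(240))), t(replicate(30, mk_row(-240))))
  rownames(vals) <- sprintf("r%d", 1:60); colnames(vals) <- offs
  mat <- tssanchor:::signal_matrix(vals, offs, 3000, 20)
  km <- kmeans_positional(mat, 2, seed = 1)
  truth <- rep(c("d", "u"), each = 30)
  expect_equal(adjusted_rand_index(km$labels, truth), 1)
  km2 <- kmeans_positional(mat, 2, seed = 1)
  expect_identical(km$labels, km2$labels)

  # k = number of distinct rows -> zero inertia
  vals3 <- rbind(mk_row(240), mk_row(-240), mk_row(2000))
  rownames(vals3) <- c("a", "b", "c"); colnames(vals3) <- offs
  km3 <- kmeans_positional(tssanchor:::signal_matrix(vals3, offs, 3000, 20),
                           3, seed = 2)
  expect_equal(km3$inertia, 0)
  expect_equal(sort(km3$sizes), c(1L, 1L, 1L))
})

test_that("cluster naming orders near-downstream clusters by amplitude", {
  offs <- seq(-3000, 3000, 20)
  mk_row <- function(at, h) { v <- numeric(length(offs)); v[offs == at] <- h; v }
  vals <- rbind(t(replicate(20, mk_row(240, 10))),
                t(replicate(20, mk_row(260, 2))),
                t(replicate(20, mk_row(-240, 5))),
                t(replicate(20, mk_row(2000, 4))))
  rownames(vals) <- sprintf("r%d", seq_len(nrow(vals))); colnames(vals) <- offs
  mat <- tssanchor:::signal_matrix(vals, offs, 3000, 20)
  km <- kmeans_positional(mat, 4, seed = 3)
  nm <- name_clusters(km)
  expect_setequal(nm$label, c("1", "2", "3", "4"))
  expect_equal(nm$role[nm$label == "1"], "near_down")
  expect_gt(nm$amplitude[nm$label == "1"], nm$amplitude[nm$label == "3"])
  expect_equal(nm$role[nm$label == "2"], "near_up")
  expect_equal(nm$role[nm$label == "4"], "far_down")
})

test_that("subclustering the combination cluster separates the far modes", {
  set.seed(71)
  offs <- seq(-3000, 3000, 20)
  jrow <- function(mu, h) {
    v <- h * exp(-(offs - mu)^2 / (2 * 150^2)); v
  }
  far_up <- t(sapply(rnorm(40, -2000, 100), jrow, h = 5))
  far_dn <- t(sapply(rnorm(40, 2000, 100), jrow, h = 5))
  over <- t(sapply(rnorm(40, 0, 80), jrow, h = 5))
  weak <- matrix(0.5, 40, length(offs)) +
    matrix(runif(40 * length(offs), 0, 0.02), 40)
  vals <- rbind(far_up, far_dn, over, weak)
  rownames(vals) <- sprintf("r%d", seq_len(nrow(vals))); colnames(vals) <- offs
  mat <- tssanchor:::signal_matrix(vals, offs, 3000, 20)
  km <- kmeans_positional(mat, 1, seed = 4)  # all rows in one cluster
  sub <- subcluster(mat, km, 1, k = 4, seed = 5)
  expect_setequal(sub$naming$role, c("far_up", "far_down", "over_tss", "weak"))
  expect_lt(sub$naming$mode[sub$naming$role == "far_up"], -1500)
  expect_gt(sub$naming$mode[sub$naming$role == "far_down"], 1500)
  expect_equal(sub$naming$sublabel, sprintf("4.%d", 1:4))
  sub2 <- subcluster(mat, km, 1, k = 4, seed = 5)
  expect_identical(sub$assignment$labels, sub2$assignment$labels)
  expect_error(subcluster(mat, km, 1, k = 200, seed = 5), "fewer rows")
})

test_that("peak width statistics are exact and match the sampling model", {
  pk <- peaks_gr("c", c(1000, 2000), width = c(100, 300))
  # peaks_gr builds summit +/- width/2 inclusive -> width + 1
  w <- peak_width_stats(pk)
  expect_equal(w$mean, 201)
  expect_equal(w$median, 201)
  expect_error(peak_width_stats(pk[0]), "empty")

  sim <- simulate_transcripts(12000, seed = 81)
  gen <- generate_peaks(sim$models, peak_mixture_config("seq"), 10000,
                        chrom_lengths = sim$chrom_lengths, seed = 82,
                        make_track = FALSE)
  ws <- peak_width_stats(gen$peaks)
  expect_lt(abs(ws$median - 1800) / 1800, 0.02)
})

test_that("track correlation is 1 for identical tracks, ~0 for noise", {
  set.seed(91)
  t1 <- binned_track(list(c1 = rexp(10000)), 20L)
  t2 <- binned_track(list(c1 = rexp(10000)), 20L)
  r <- sample_correlation(list(a = t1, b = t1, c = t2))
  expect_equal(unname(r$r["a", "b"]), 1)
  expect_lt(abs(r$r["a", "c"]), 0.05)
  flat <- binned_track(list(c1 = rep(2, 10000)), 20L)
  rf <- sample_correlation(list(a = t1, flat = flat))
  expect_true("flat" %in% rf$flagged)
  expect_true(is.na(rf$r["a", "flat"]))
})

test_that("group comparison recovers a planted signal ratio", {
  offs <- seq(-1000, 1000, 20)
  va <- matrix(3, 10, length(offs)); vb <- matrix(1, 10, length(offs))
  vals <- rbind(va, vb)
  rownames(vals) <- sprintf("r%d", 1:20); colnames(vals) <- offs
  mat <- tssanchor:::signal_matrix(vals, offs, 1000, 20)
  cmp <- compare_group_signal(mat, sprintf("r%d", 1:10), sprintf("r%d", 11:20))
  expect_equal(cmp$ratio, 3)
  identical_cmp <- compare_group_signal(mat, "r1", "r2")
  expect_equal(identical_cmp$ratio, 1)
  vals0 <- vals; vals0[11:20, ] <- 0
  mat0 <- tssanchor:::signal_matrix(vals0, offs, 1000, 20)
  cmp0 <- compare_group_signal(mat0, sprintf("r%d", 1:10),
                               sprintf("r%d", 11:20))
  expect_true(cmp0$flagged)
  expect_error(compare_group_signal(mat, "r1", "r1"), ".")
})

test_that("profiles are invariant under genome coordinate reversal", {
  # a genome flip (reverse coordinates, flip strands) must leave every
  # TSS-relative profile unchanged
  L <- 20000L; bs <- 20L
  tr <- binned_track(list(c1 = numeric(L / bs)), bs)
  tss <- 10010
  tr$values$c1[ceiling((tss + 250) / bs)] <- 2   # mid-bin impulse at +250
  m_fwd <- build_signal_matrix(tr, anchor_df("c1", tss, "+"), window = 2000)
  # flipped genome: position p -> L + 1 - p; the impulse bin reverses too
  tr_rev <- binned_track(list(c1 = rev(tr$values$c1)), bs)
  tss_rev <- L + 1L - tss
  m_rev <- build_signal_matrix(tr_rev, anchor_df("c1", tss_rev, "-"),
                               window = 2000)
  expect_equal(unname(m_fwd$values), unname(m_rev$values))
})
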