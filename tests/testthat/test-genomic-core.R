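test_that("TSS distances follow the downstream-positive convention", {
  expect_equal(tss_distance(1000, 1000, "+"), 0)
  expect_equal(tss_distance(5000, 5000, "-"), 0)
  expect_equal(tss_distance(1240, 1000, "+"), 240)
  expect_equal(tss_distance(4760, 5000, "-"), 240)
  expect_equal(tss_distance(40, 100, "-"), 60)
  expect_error(tss_distance(10, 10, "*"), "strand")
})

test_that("flipping the strand negates the TSS distance", {
  set.seed(42)
  summit <- sample.int(100000, 500)
  tss <- sample.int(100000, 500)
  expect_equal(tss_distance(summit, tss, "+"),
               -tss_distance(summit, tss, "-"))
})

test_that("nearest-TSS assignment picks the minimal distance with stated ties", {
  tx <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1000, 5000), c(3000, 7000)), "+",
    gene_id = c("g1", "g2"), transcript_id = c("t1", "t2"))
  tm <- transcript_models(tx)
  ann <- assign_nearest_tss(peaks_gr("chr1", c(1240, 3000)), tm)
  expect_equal(ann$transcript_id, c("t1", "t1"))  # midway tie -> smaller id
  expect_equal(ann$distance, c(240, 2000))

  tx2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 100), "-",
                                gene_id = "g", transcript_id = "t")
  ann2 <- assign_nearest_tss(peaks_gr("chr1", 40), transcript_models(tx2))
  expect_equal(ann2$distance, 60)

  expect_error(assign_nearest_tss(peaks_gr("chr1", 40),
                                  transcript_models(tx[0])), "empty")
  ann3 <- assign_nearest_tss(peaks_gr("chrX", 40), tm)
  expect_true(ann3$unassigned)
})

test_that("nearest-TSS agrees with a brute-force scan on random peaks", {
  set.seed(7)
  sim <- simulate_transcripts(300, spacing = 2000, n_chroms = 2L, seed = 7)
  tdf <- tss_of(sim$models)
  summits <- sample.int(600000, 1000)
  chroms <- sample(unique(tdf$chrom), 1000, replace = TRUE)
  ann <- assign_nearest_tss(peaks_gr(chroms, summits), sim$models)
  for (i in sample(1000, 200)) {  # spot-check a random subset exhaustively
    cand <- tdf[tdf$chrom == chroms[i], ]
    d <- abs(tss_distance(summits[i], cand$tss, cand$strand))
    best <- cand$transcript_id[d == min(d)]
    expect_equal(abs(ann$distance[i]), min(d))
    expect_equal(ann$transcript_id[i], min(best))
  }
})

test_that("promoter classification uses an inclusive window", {
  expect_equal(classify_peak_location(240), "promoter")
  expect_equal(classify_peak_location(-1500), "non-promoter")
  expect_equal(classify_peak_location(-1000), "promoter")
  expect_equal(classify_peak_location(1000), "promoter")
  expect_equal(classify_peak_location(1001), "non-promoter")
})

test_that("CGI promoter classification requires >=1 bp overlap", {
  tx <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 3000), "+",
                               gene_id = "g", transcript_id = "t")
  tm <- transcript_models(tx)
  w <- c(500, 500)
  # overlap; far away; exactly abutting (BED half-open [1500,2000) starts
  # one past the closed window end 1500)
  cgi_hit <- read_bed_text("chr1\t900\t1400")
  cgi_far <- read_bed_text("chr1\t5000\t5200")
  cgi_abut <- read_bed_text("chr1\t1500\t2000")
  expect_equal(unname(classify_cgi_promoter(tm, cgi_hit, w)), "CGI")
  expect_equal(unname(classify_cgi_promoter(tm, cgi_far, w)), "non-CGI")
  expect_equal(unname(classify_cgi_promoter(tm, cgi_abut, w)), "non-CGI")
})

test_that("gene-region classes follow the stated priority and partition", {
  tm <- toy_models()
  expect_equal(classify_gene_region(1100, tm, "tA"), "5'UTR")
  expect_equal(classify_gene_region(1300, tm, "tA"), "first_coding_exon")
  expect_equal(classify_gene_region(1800, tm, "tA"), "first_intron")
  expect_equal(classify_gene_region(3500, tm, "tA"), "other_transcribed")
  expect_equal(classify_gene_region(701, tm, "tA"), "upstream")
  expect_equal(classify_gene_region(10500, tm, "tB"), "intergenic")
  # minus strand mirror
  expect_equal(classify_gene_region(8900, tm, "tB"), "5'UTR")
  expect_equal(classify_gene_region(8500, tm, "tB"), "first_coding_exon")
  expect_equal(classify_gene_region(8000, tm, "tB"), "first_intron")
  expect_equal(classify_gene_region(6500, tm, "tB"), "other_transcribed")
  expect_equal(classify_gene_region(9300, tm, "tB"), "upstream")
  # every position maps to exactly one class
  pos <- seq(1, 9999, by = 7)
  cls <- classify_gene_region(pos, tm, "tA")
  expect_true(all(cls %in% c("5'UTR", "first_coding_exon", "first_intron",
                             "other_transcribed", "upstream", "intergenic")))
  expect_equal(length(cls), length(pos))
})

test_that("transcripts without CDS collapse exonic 5' classes", {
  tx <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 2000), "+",
                               gene_id = "g", transcript_id = "t")
  u <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 1200), "+",
                              transcript_id = "t")
  tm <- transcript_models(tx, utr5 = u)
  expect_equal(classify_gene_region(1100, tm, "t"), "5'-exonic")
})

test_that("closed-interval overlap matches the exhaustive small-coordinate oracle", {
  grid <- expand.grid(s1 = 0:9, e1 = 0:9, s2 = 0:9, e2 = 0:9)
  grid <- grid[grid$s1 <= grid$e1 & grid$s2 <= grid$e2, ]
  ours <- with(grid, tssanchor:::interval_overlap(s1, e1, s2, e2))
  oracle <- mapply(function(s1, e1, s2, e2)
    length(intersect(s1:e1, s2:e2)), grid$s1, grid$e1, grid$s2, grid$e2)
  expect_equal(ours, unname(oracle))
  # overlap > 0 <=> start1 <= end2 and start2 <= end1
  expect_equal(ours > 0, with(grid, s1 <= e2 & s2 <= e1))
})

test_that("gene-level binding keeps the strongest promoter peak per gene", {
  tx <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1000, 9000), c(3000, 11000)), "+",
    gene_id = c("g1", "g2"), transcript_id = c("t1", "t2"))
  tm <- transcript_models(tx)
  pk <- peaks_gr("chr1", c(1240, 900, 9100, 15000), score = c(5, 9, 2, 7))
  ann <- assign_nearest_tss(pk, tm)
  clus <- c(p1 = "1", p2 = "2", p3 = "4", p4 = "1")
  b <- gene_level_binding(ann, clusters = clus)
  expect_setequal(b$gene_id, c("g1", "g2"))
  expect_equal(b$category[b$gene_id == "g1"], "2")  # score 9 beats 5
  expect_equal(b$category[b$gene_id == "g2"], "4")
  # peak p4 at +6000 of t2 is outside the promoter window: g2 only via p3
  expect_equal(b$best_peak[b$gene_id == "g2"], "p3")
})
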