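# Hand-built transcript models with fully known coordinates.
#
# chrT, length 10000:
#   gA/tA (+): span 1001..4000, TSS 1001
#     5'UTR 1001..1200, CDS1 1201..1500, intron1 1501..2300,
#     CDS2 2301..2800, intron2 2801..3300, CDS3 3301..4000
#   gB/tB (-): span 6001..9000, TSS 9000
#     5'UTR 8801..9000, CDS1 8301..8800, intron1 7501..8300, CDS2 6001..7500
toy_models <- function() {
  tx <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(c(1001, 6001), c(4000, 9000)), c("+", "-"),
    gene_id = c("gA", "gB"), transcript_id = c("tA", "tB"))
  utr5 <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(c(1001, 8801), c(1200, 9000)), c("+", "-"),
    transcript_id = c("tA", "tB"))
  cds <- GenomicRanges::GRanges(
    "chrT",
    IRanges::IRanges(c(1201, 2301, 3301, 8301, 6001),
                     c(1500, 2800, 4000, 8800, 7500)),
    c("+", "+", "+", "-", "-"),
    transcript_id = c("tA", "tA", "tA", "tB", "tB"),
    rank = c(1L, 2L, 3L, 1L, 2L))
  introns <- GenomicRanges::GRanges(
    "chrT",
    IRanges::IRanges(c(1501, 2801, 7501), c(2300, 3300, 8300)),
    c("+", "+", "-"),
    transcript_id = c("tA", "tA", "tB"), rank = c(1L, 2L, 1L))
  transcript_models(tx, utr5 = utr5, cds = cds, introns = introns)
}

peaks_gr <- function(chrom, summit, score = 1, width = 200,
                     name = sprintf("p%d", seq_along(summit))) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(summit - width / 2,
                                          summit + width / 2),
                         name = name, summit = as.integer(summit),
                         score = score)
}

# naive O(n*m) IUPAC sliding-window matcher used as the scanning oracle
IUPAC_MAP <- list(A = "A", C = "C", G = "G", T = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))

naive_scan <- function(seq, pattern, both = TRUE) {
  match_at <- function(s, pat) {
    sv <- strsplit(s, "")[[1]]
    pv <- strsplit(pat, "")[[1]]
    m <- length(pv); n <- length(sv)
    if (n < m) return(integer(0))
    hits <- integer(0)
    for (i in 0:(n - m)) {
      ok <- TRUE
      for (j in seq_len(m)) {
        base <- sv[i + j]
        if (base == "N" || !(base %in% IUPAC_MAP[[pv[j]]])) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, i)
    }
    hits
  }
  revcomp <- function(p) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
              W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
              N = "N")
    paste(rev(comp[strsplit(p, "")[[1]]]), collapse = "")
  }
  hp <- match_at(seq, pattern)
  out <- data.frame(offset = hp, strand = rep("+", length(hp)))
  if (both) {
    rc <- revcomp(pattern)
    if (rc != pattern) {
      hm <- match_at(seq, rc)
      out <- rbind(out, data.frame(offset = hm,
                                   strand = rep("-", length(hm))))
    }
  }
  out[order(out$offset, out$strand), , drop = FALSE]
}

read_bed_text <- function(lines) {
  f <- tempfile(fileext = ".bed")
  writeLines(lines, f)
  on.exit(unlink(f))
  read_bed(f)
}

random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# cached default-scale demo for the acceptance suite (run once)
demo_cache <- new.env(parent = emptyenv())
get_demo <- function() {
  if (is.null(demo_cache$res))
    demo_cache$res <- run_synthetic_demo(seed = 1L)
  demo_cache$res
}

small_demo_config <- function() {
  demo_config(n_peaks = 800L, n_genes = 1000L, n_direct = 60L,
              n_indirect = 60L, n_motif_regions = 300L,
              genome = genome_config(n_chroms = 1L, chrom_length = 250000L,
                                     n_genes = 30L),
              expression = expression_design(reps = 2L))
}
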