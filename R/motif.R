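IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

#' Motif specification
#'
#' @param name Short motif name.
#' @param pattern String over IUPAC nucleotide codes, length >= 2. Degenerate
#'   codes expand during scanning, but `N` in the *scanned sequence* never
#'   matches.
#' @param scan_strands `"both"` (default; TF motifs are orientation-free on
#'   double-stranded DNA) or `"forward"`.
#' @return A list of class `MotifSpec`.
#' @examples
#' motif_spec("znf711", "AGGCCTAG")
#' motif_spec("short", "GGCCT")
#' @export
motif_spec <- function(name, pattern, scan_strands = c("both", "forward")) {
  scan_strands <- match.arg(scan_strands)
  pattern <- toupper(pattern)
  if (nchar(pattern) < 2L) stop("pattern length must be >= 2")
  if (!all(strsplit(pattern, "")[[1]] %in% IUPAC_LETTERS))
    stop("pattern contains non-IUPAC letters")
  structure(list(name = name, pattern = pattern, scan_strands = scan_strands),
            class = "MotifSpec")
}

as_motif_list <- function(motifs) {
  if (inherits(motifs, "MotifSpec")) motifs <- list(motifs)
  stopifnot(all(vapply(motifs, inherits, logical(1), "MotifSpec")))
  motifs
}

#' Scan sequences for a motif
#'
#' Reports every occurrence of the pattern (and, for both-strand scans, of
#' its reverse complement) with 0-based forward-strand offsets. Overlapping
#' occurrences are all reported. `N` in the subject never matches.
#'
#' @param sequences Named `DNAStringSet` or character vector over
#'   `A,C,G,T,N`.
#' @param motif A [motif_spec()] object (or bare pattern string).
#' @return data.frame: `seqname`, `offset` (0-based, forward strand),
#'   `strand`.
#' @export
scan_motif <- function(sequences, motif) {
  if (is.character(motif)) motif <- motif_spec(motif, motif)
  if (is.character(sequences)) {
    if (any(grepl("[^ACGTNacgtn]", sequences)))
      stop("sequences contain letters outside A/C/G/T/N")
    sequences <- DNAStringSet(toupper(sequences))
  }
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%d", seq_along(sequences))
  hits_of <- function(pattern, strand) {
    mi <- vmatchPattern(pattern, sequences, fixed = "subject")
    pieces <- lapply(seq_along(mi), function(i) {
      ir <- mi[[i]]
      if (length(ir) == 0L) return(NULL)
      data.frame(seqname = names(sequences)[i], offset = start(ir) - 1L,
                 strand = strand, stringsAsFactors = FALSE)
    })
    do.call(rbind, pieces)
  }
  out <- hits_of(motif$pattern, "+")
  if (motif$scan_strands == "both") {
    rc <- as.character(reverseComplement(DNAString(motif$pattern)))
    if (rc != motif$pattern) out <- rbind(out, hits_of(rc, "-"))
  }
  if (is.null(out))
    out <- data.frame(seqname = character(), offset = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  out[order(out$seqname, out$offset, out$strand), , drop = FALSE]
}

#' Select the highest-scoring peaks
#'
#' @param peaks `GRanges` with a `score` column.
#' @param n How many to keep; ties broken by earlier genomic coordinate.
#'   When fewer than `n` peaks exist, all are returned with a warning.
#' @return `GRanges` subset ordered by descending score.
#' @export
select_top_peaks <- function(peaks, n = 5000L) {
  stopifnot("score" %in% names(mcols(peaks)))
  if (length(peaks) < n) {
    warning("only ", length(peaks), " peaks available (requested ", n, ")")
    n <- length(peaks)
  }
  o <- order(-peaks$score, as.character(seqnames(peaks)), start(peaks))
  peaks[o[seq_len(n)]]
}

#' Sample width-matched random regions from CpG-island promoters
#'
#' Draws `n` intervals of exactly `width` bp, each fully inside a uniformly
#' chosen source region (sampling with replacement across sources) at a
#' uniformly chosen offset. This is the randomized background for motif
#' coverage: GC-matched because it comes from the same island-promoter
#' compartment as the peaks.
#'
#' @param sources `GRanges` of CpG-island promoter intervals; every region
#'   used must be at least `width` bp (shorter sources are skipped; if none
#'   remain this is an error).
#' @param width Region width (bp).
#' @param n Number of regions.
#' @param seed Integer seed.
#' @return `GRanges` of `n` sampled intervals.
#' @export
sample_matched_random_regions <- function(sources, width, n = 5000L,
                                          seed = 1L) {
  ok <- IRanges::width(sources) >= width
  if (!any(ok)) stop("no source region is at least ", width, " bp")
  src <- sources[ok]
  set.seed(seed)
  ix <- sample(length(src), n, replace = TRUE)
  slack <- IRanges::width(src)[ix] - width
  off <- floor(runif(n) * (slack + 1L))
  st <- start(src)[ix] + off
  GRanges(seqnames(src)[ix], IRanges(st, st + width - 1L))
}

#' Fraction of regions containing each motif
#'
#' @param regions `GRanges` (must lie within the sequences).
#' @param sequences Named `DNAStringSet` genome.
#' @param motifs A [motif_spec()] or list of them.
#' @param set_name Label recorded in the report.
#' @return A `MotifCoverageReport` data.frame: `set`, `width_class`,
#'   `motif`, `n`, `fraction`.
#' @export
motif_coverage <- function(regions, sequences, motifs, set_name = "regions") {
  motifs <- as_motif_list(motifs)
  if (length(regions) == 0L) stop("empty region set")
  seqlens <- setNames(nchar(as.character(sequences)), names(sequences))
  chr <- as.character(seqnames(regions))
  if (!all(chr %in% names(seqlens)))
    stop("region on unknown sequence: ",
         paste(unique(setdiff(chr, names(seqlens))), collapse = ","))
  over <- which(end(regions) > seqlens[chr] | start(regions) < 1L)
  if (length(over))
    stop("region outside sequence bounds: index ",
         paste(head(over, 5), collapse = ","))
  segs <- extract_region_seqs(regions, sequences)
  rows <- lapply(motifs, function(m) {
    hit <- count_hits(segs, m) > 0
    data.frame(set = set_name,
               width_class = as.integer(round(mean(IRanges::width(regions)))),
               motif = m$name, n = length(regions),
               fraction = mean(hit), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("MotifCoverageReport", class(out))
  out
}

extract_region_seqs <- function(regions, sequences) {
  chrs <- as.character(seqnames(regions))
  segs <- rep(DNAStringSet("A"), length(regions))
  for (chr in unique(chrs)) {
    ix <- which(chrs == chr)
    segs[ix] <- DNAStringSet(sequences[[chr]],
                             start = start(regions)[ix],
                             end = end(regions)[ix])
  }
  segs
}

count_hits <- function(segs, motif) {
  n <- vcountPattern(motif$pattern, segs, fixed = "subject")
  if (motif$scan_strands == "both") {
    rc <- as.character(reverseComplement(DNAString(motif$pattern)))
    if (rc != motif$pattern)
      n <- n + vcountPattern(rc, segs, fixed = "subject")
  }
  n
}

#' Motif coverage of summit windows (ChExMix-style)
#'
#' Builds `summit +/- flank` windows (2*flank+1 nt) and computes motif
#' coverage on them. Windows truncated at sequence boundaries are kept and
#' flagged.
#'
#' @param summits data.frame with `chrom` and `pos` (1-based), or `GRanges`
#'   with a `summit` column.
#' @param sequences Named `DNAStringSet`.
#' @param motifs Motif spec(s).
#' @param flank Flank size (bp); 10 gives the 21-nt windows used for
#'   single-base summit calls.
#' @return A `MotifCoverageReport` with attribute `truncated` (count).
#' @export
chexmix_window_coverage <- function(summits, sequences, motifs, flank = 10L) {
  if (is(summits, "GRanges"))
    summits <- data.frame(chrom = as.character(seqnames(summits)),
                          pos = summits$summit)
  seqlens <- setNames(nchar(as.character(sequences)), names(sequences))
  st <- summits$pos - flank
  en <- summits$pos + flank
  trunc <- sum(st < 1L | en > seqlens[summits$chrom])
  st <- pmax(st, 1L)
  en <- pmin(en, seqlens[summits$chrom])
  win <- GRanges(summits$chrom, IRanges(st, en))
  rep <- motif_coverage(win, sequences, motifs,
                        set_name = sprintf("summit_pm%d", flank))
  attr(rep, "truncated") <- trunc
  rep
}

#' Motif coverage across width classes with nested sampling
#'
#' Samples `n` regions at the largest width from the CpG-island promoter
#' sources, then takes centred sub-regions at each smaller width, so the
#' width classes are nested and coverage is non-decreasing in width by
#' construction. One report row per width and motif, plus a monotonicity
#' diagnostic.
#'
#' @param sources `GRanges` of CpG-island promoter intervals.
#' @param sequences Named `DNAStringSet`.
#' @param motifs Motif spec(s).
#' @param widths Width classes (bp/nt), any order.
#' @param n Regions per width class.
#' @param seed Integer seed.
#' @param nested Use nested sub-regions (`TRUE`) or independent draws per
#'   width (`FALSE`).
#' @return A `MotifCoverageReport` with attribute `monotone` (logical per
#'   motif).
#' @export
width_coverage_curve <- function(sources, sequences, motifs,
                                 widths = c(20L, 200L, 2000L), n = 5000L,
                                 seed = 1L, nested = TRUE) {
  motifs <- as_motif_list(motifs)
  widths <- sort(as.integer(widths))
  wmax <- max(widths)
  base <- sample_matched_random_regions(sources, wmax, n = n, seed = seed)
  reports <- lapply(seq_along(widths), function(i) {
    w <- widths[i]
    regions <- if (nested) {
      shift <- floor((wmax - w) / 2)
      GRanges(seqnames(base), IRanges(start(base) + shift,
                                      start(base) + shift + w - 1L))
    } else {
      sample_matched_random_regions(sources, w, n = n, seed = seed + i)
    }
    motif_coverage(regions, sequences, motifs,
                   set_name = sprintf("random_cgi_%dnt", w))
  })
  out <- do.call(rbind, reports)
  class(out) <- c("MotifCoverageReport", "data.frame")
  mono <- vapply(motifs, function(m) {
    fr <- out$fraction[out$motif == m$name][order(widths)]
    all(diff(fr) >= 0)
  }, logical(1))
  names(mono) <- vapply(motifs, `[[`, character(1), "name")
  attr(out, "monotone") <- mono
  out
}
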