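#' Binned genome-wide coverage track
#'
#' A dense representation of coverage: one numeric vector per chromosome,
#' with bin `i` covering positions `[(i-1)*binsize + 1, i*binsize]`. This is
#' the input contract for all signal operations; bedGraph input is rasterized
#' onto this grid on read.
#'
#' @param values Named list of numeric vectors, one per chromosome.
#' @param binsize Bin width in bp.
#' @return An object of class `BinnedTrack`.
#' @export
binned_track <- function(values, binsize = 20L) {
  stopifnot(is.list(values), !is.null(names(values)), binsize >= 1)
  if (any(vapply(values, function(v) any(v < 0), logical(1))))
    stop("coverage values must be non-negative")
  structure(list(values = values, binsize = as.integer(binsize)),
            class = "BinnedTrack")
}

#' @export
print.BinnedTrack <- function(x, ...) {
  cat(sprintf("BinnedTrack: %d chromosome(s), binsize %d bp, %.3g total signal\n",
              length(x$values), x$binsize,
              sum(vapply(x$values, sum, numeric(1)))))
  invisible(x)
}

#' Chromosome lengths (in bp) spanned by a track
#' @param track A [binned_track()] object.
#' @return Named integer vector.
#' @export
track_lengths <- function(track) {
  vapply(track$values, length, integer(1)) * track$binsize
}

# value of the bin containing each absolute position; 0 outside the track
track_value_at <- function(track, chrom, pos) {
  v <- track$values[[chrom]]
  if (is.null(v)) return(rep(0, length(pos)))
  idx <- ceiling(pos / track$binsize)
  ok <- idx >= 1L & idx <= length(v) & pos >= 1L
  out <- numeric(length(pos))
  out[ok] <- v[idx[ok]]
  out
}

#' Add a triangular peak kernel onto a track
#'
#' The kernel has height `score` at the summit, falling linearly to zero at
#' `summit +/- width/2`, evaluated at bin centers.
#'
#' @param track A [binned_track()] object (modified copy returned).
#' @param chrom,summit,score,width Parallel vectors describing the peaks.
#' @return The updated `BinnedTrack`.
#' @export
add_peak_kernels <- function(track, chrom, summit, score, width) {
  bs <- track$binsize
  n <- length(summit)
  chrom <- rep_len(as.character(chrom), n)
  score <- rep_len(score, n)
  width <- rep_len(width, n)
  # accumulate per chromosome into a local vector: modifying the list
  # element directly would copy the whole chromosome every iteration
  for (chr in unique(chrom)) {
    v <- track$values[[chr]]
    if (is.null(v)) next
    nb <- length(v)
    for (i in which(chrom == chr)) {
      half <- width[i] / 2
      lo <- max(1L, ceiling((summit[i] - half) / bs))
      hi <- min(nb, ceiling((summit[i] + half) / bs))
      if (lo > hi) next
      centers <- (lo:hi - 0.5) * bs
      v[lo:hi] <- v[lo:hi] + score[i] * pmax(0, 1 - abs(centers - summit[i]) / half)
    }
    track$values[[chr]] <- v
  }
  track
}

#' Convert a track to bedGraph-style GRanges
#'
#' Zero-signal bins are dropped, matching sparse bedGraph convention.
#' @param track A [binned_track()] object.
#' @return `GRanges` with a `score` column.
#' @export
track_as_granges <- function(track) {
  bs <- track$binsize
  pieces <- lapply(names(track$values), function(chr) {
    v <- track$values[[chr]]
    nz <- which(v != 0)
    if (!length(nz)) return(GRanges())
    GRanges(chr, IRanges((nz - 1L) * bs + 1L, nz * bs), score = v[nz])
  })
  out <- suppressWarnings(do.call(c, pieces))
  out
}

#' Rasterize interval scores onto a binned grid
#'
#' Each bin takes the coverage-weighted mean of overlapping interval scores
#' (intervals are assumed disjoint, as in bedGraph).
#'
#' @param gr `GRanges` with a numeric `score` column.
#' @param binsize Bin width (bp).
#' @param chrom_lengths Optional named vector of chromosome lengths; defaults
#'   to the rightmost covered position per chromosome.
#' @return A [binned_track()] object.
#' @export
rasterize_track <- function(gr, binsize = 20L, chrom_lengths = NULL) {
  stopifnot(is(gr, "GRanges"), "score" %in% names(mcols(gr)))
  chroms <- unique(as.character(seqnames(gr)))
  if (is.null(chrom_lengths))
    chrom_lengths <- vapply(chroms, function(chr)
      max(end(gr[seqnames(gr) == chr])), numeric(1))
  vals <- lapply(chroms, function(chr) {
    g <- gr[seqnames(gr) == chr]
    nb <- ceiling(chrom_lengths[[chr]] / binsize)
    acc <- numeric(nb)
    cover <- numeric(nb)
    b1 <- ceiling(start(g) / binsize)
    b2 <- ceiling(end(g) / binsize)
    for (i in seq_along(g)) {
      bins <- b1[i]:b2[i]
      ov <- interval_overlap(start(g)[i], end(g)[i],
                             (bins - 1L) * binsize + 1L, bins * binsize)
      keep <- bins <= nb
      acc[bins[keep]] <- acc[bins[keep]] + g$score[i] * ov[keep]
      cover[bins[keep]] <- cover[bins[keep]] + ov[keep]
    }
    out <- numeric(nb)
    nz <- cover > 0
    out[nz] <- acc[nz] / cover[nz]
    out
  })
  names(vals) <- chroms
  binned_track(vals, binsize)
}
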