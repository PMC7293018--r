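#' TSS-anchored signal matrix from a coverage track
#'
#' One row per anchor, one column per TSS-relative bin. Bins are centred on
#' multiples of `binsize` from `-window` to `+window` (so there are
#' `2*window/binsize + 1` bins, with the centre bin sitting on the TSS),
#' and minus-strand rows are reversed so columns always read upstream to
#' downstream in transcription direction. Bins off the end of a chromosome
#' read 0; anchors on chromosomes absent from the track are dropped with a
#' recorded count.
#'
#' @param track A [binned_track()] object.
#' @param anchors data.frame with `chrom`, `tss`, `strand` and an id column
#'   (`transcript_id` or `peak`), e.g. from [tss_of()] or
#'   [assign_nearest_tss()] joined to TSS positions.
#' @param window Half-window (bp).
#' @param binsize Bin width (bp); must divide `window`.
#' @param id_col Column of `anchors` naming rows.
#' @return A `SignalMatrix`: list with `values` (matrix), `offsets` (bin
#'   centre offsets, bp), `window`, `binsize`, `normalization`, `dropped`.
#' @export
build_signal_matrix <- function(track, anchors, window = 3000L,
                                binsize = track$binsize,
                                id_col = intersect(c("peak", "transcript_id"),
                                                   names(anchors))[1]) {
  stopifnot(inherits(track, "BinnedTrack"), window %% binsize == 0)
  offsets <- seq(-window, window, by = binsize)
  keep <- anchors$chrom %in% names(track$values)
  dropped <- sum(!keep)
  if (dropped) warning(dropped, " anchors on chromosomes absent from track")
  anchors <- anchors[keep, , drop = FALSE]
  vals <- matrix(0, nrow(anchors), length(offsets),
                 dimnames = list(anchors[[id_col]], offsets))
  for (i in seq_len(nrow(anchors))) {
    sgn <- if (anchors$strand[i] == "+") 1 else -1
    pos <- anchors$tss[i] + sgn * offsets
    vals[i, ] <- track_value_at(track, anchors$chrom[i], pos)
  }
  signal_matrix(vals, offsets, window, binsize, dropped = dropped)
}

signal_matrix <- function(values, offsets, window, binsize,
                          normalization = "none", dropped = 0L) {
  structure(list(values = values, offsets = offsets, window = window,
                 binsize = binsize, normalization = normalization,
                 dropped = dropped),
            class = "SignalMatrix")
}

#' @export
print.SignalMatrix <- function(x, ...) {
  cat(sprintf("SignalMatrix: %d rows x %d bins (+/-%d bp at %d bp), norm=%s\n",
              nrow(x$values), ncol(x$values), x$window, x$binsize,
              x$normalization))
  invisible(x)
}

#' Per-peak kernel signal matrix
#'
#' Rows are individual peaks; row `i` is peak `i`'s own triangular kernel
#' (height = score, half-width = width/2) evaluated at TSS-relative bin
#' centres of its anchor TSS. This attributes signal to the peak that
#' produced it, which is what positional clustering of peaks needs when
#' several peaks share a neighbourhood.
#'
#' @param peaks `GRanges` with `summit` and `score`.
#' @param anchors data.frame parallel to `peaks` with `tss` and `strand`
#'   (e.g. the nearest-TSS annotation joined to TSS positions).
#' @inheritParams build_signal_matrix
#' @return A `SignalMatrix`.
#' @export
peak_signal_matrix <- function(peaks, anchors, window = 3000L, binsize = 20L) {
  stopifnot(length(peaks) == nrow(anchors), window %% binsize == 0)
  offsets <- seq(-window, window, by = binsize)
  d <- tss_distance(peaks$summit, anchors$tss, anchors$strand)
  half <- width(peaks) / 2
  vals <- outer(rep(1, length(peaks)), offsets)
  vals <- peaks$score * pmax(0, 1 - abs(vals - d) / half)
  rn <- if (!is.null(peaks$name)) peaks$name else sprintf("peak_%d", seq_along(peaks))
  dimnames(vals) <- list(rn, offsets)
  signal_matrix(vals, offsets, window, binsize)
}

#' Tag-density profile with mode and shoulder detection
#'
#' Column means of a signal matrix (or a summit histogram) as a function of
#' TSS-relative position. Modes are detected on the 5-bin moving-average
#' smoothed profile, which stabilises the arg-max against per-bin counting
#' noise; within a tied smoothed plateau the bin with the highest raw
#' density wins, remaining ties resolve toward positive (downstream)
#' offsets. The shoulder is the largest smoothed local maximum on the
#' opposite side of the TSS from the primary mode.
#'
#' @param x A `SignalMatrix`, or a numeric vector of per-bin densities
#'   named/accompanied by offsets.
#' @param offsets Bin centre offsets when `x` is a bare vector.
#' @param smooth_bins Moving-average width (bins) for shoulder detection.
#' @return A `DensityProfile`: list with `offsets`, `density`,
#'   `primary_mode`, `shoulder`, `flagged` (TRUE when all-zero input made
#'   the modes undefined).
#' @export
tag_density_profile <- function(x, offsets = NULL, smooth_bins = 5L) {
  if (inherits(x, "SignalMatrix")) {
    dens <- colMeans(x$values)
    offsets <- x$offsets
  } else {
    dens <- as.numeric(x)
    if (is.null(offsets)) offsets <- as.numeric(names(x))
  }
  if (all(dens == 0) || all(!is.finite(dens)))
    return(structure(list(offsets = offsets, density = dens,
                          primary_mode = NA_real_, shoulder = NA_real_,
                          flagged = TRUE), class = "DensityProfile"))
  sm <- moving_average(dens, smooth_bins)
  pick_mode <- function(sel) {
    best <- max(sm[sel])
    cand <- which(sel & sm == best)
    cand <- cand[dens[cand] == max(dens[cand])]  # raw density breaks plateau
    max(offsets[cand])                           # then ties go downstream
  }
  primary <- pick_mode(rep(TRUE, length(sm)))
  opp <- if (primary >= 0) offsets < 0 else offsets > 0
  shoulder <- NA_real_
  lm <- local_maxima(sm) & opp
  if (any(lm)) shoulder <- pick_mode(lm)
  structure(list(offsets = offsets, density = dens, primary_mode = primary,
                 shoulder = shoulder, flagged = FALSE),
            class = "DensityProfile")
}

#' @export
print.DensityProfile <- function(x, ...) {
  cat(sprintf("DensityProfile: %d bins, primary mode %s bp, shoulder %s bp\n",
              length(x$offsets), format(x$primary_mode), format(x$shoulder)))
  invisible(x)
}

moving_average <- function(v, k) {
  if (k <= 1L) return(v)
  n <- length(v)
  out <- numeric(n)
  h <- k %/% 2L
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    out[i] <- mean(v[lo:hi])
  }
  out
}

local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(rep(FALSE, n))
  c(FALSE, v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n], FALSE)
}

#' Histogram of summit positions relative to the TSS
#'
#' @param annotations data.frame from [assign_nearest_tss()] (uses the
#'   `distance` column).
#' @param window Half-window (bp); distances outside are dropped.
#' @param binsize Bin width (bp).
#' @return A `DensityProfile` of summit frequencies.
#' @export
summit_histogram <- function(annotations, window = 3000L, binsize = 20L) {
  offsets <- seq(-window, window, by = binsize)
  d <- annotations$distance[!annotations$unassigned]
  d <- d[abs(d) <= window + binsize / 2]
  idx <- round(d / binsize) + window / binsize + 1L
  counts <- tabulate(idx, nbins = length(offsets))
  names(counts) <- offsets
  tag_density_profile(counts, offsets)
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  ix <- sample.int(n, 1L)
  centers[1, ] <- x[ix, ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    p <- d2 / sum(d2)
    ix <- sample.int(n, 1L, prob = p)
    centers[j, ] <- x[ix, ]
    dj <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  centers
}

#' K-means clustering of TSS-anchored profiles
#'
#' Rows are divided by their maximum before clustering so that clusters
#' reflect shape and position rather than absolute depth (all-zero rows are
#' dropped and reported); amplitude re-enters through cluster ordering:
#' labels are renumbered 1..k by descending mean total (unnormalized) row
#' signal, so cluster 1 is the strongest. Lloyd iterations with k-means++
#' seeding from the given seed make the result reproducible.
#'
#' @param mat A `SignalMatrix`.
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param iter_max Maximum Lloyd iterations.
#' @param nstart Independent k-means++ restarts; the solution with the
#'   lowest within-cluster sum of squares is kept. Restarts guard against
#'   the occasional poor local optimum of a single Lloyd run.
#' @return A `ClusterAssignment`: list with `labels` (named integer vector),
#'   `sizes`, `centroids` (k x bins, normalized scale), `amplitude`
#'   (per-cluster mean raw total signal), `inertia`, `seed`, `dropped`.
#' @export
kmeans_positional <- function(mat, k, seed = 1L, iter_max = 100L,
                              nstart = 8L) {
  stopifnot(inherits(mat, "SignalMatrix"), nstart >= 1L)
  v <- mat$values
  rmax <- apply(v, 1, max)
  keep <- rmax > 0
  if (sum(keep) < k) stop("fewer non-empty rows than clusters")
  vn <- v[keep, , drop = FALSE] / rmax[keep]
  km <- NULL
  for (st in seq_len(nstart)) {
    set.seed(seed + (st - 1L) * 7919L)
    init <- kmeanspp_init(vn, k)
    cand <- suppressWarnings(kmeans(vn, centers = init, iter.max = iter_max,
                                    algorithm = "Lloyd"))
    if (is.null(km) || cand$tot.withinss < km$tot.withinss) km <- cand
  }
  if (length(unique(km$cluster)) < k)
    warning("degenerate clustering: fewer than k distinct centroids")
  raw_total <- rowSums(v[keep, , drop = FALSE])
  amp <- tapply(raw_total, km$cluster, mean)
  ord <- order(-amp)                          # 1 = strongest
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  labels <- relabel[km$cluster]
  names(labels) <- rownames(vn)
  centroids <- km$centers[ord, , drop = FALSE]
  rownames(centroids) <- seq_len(k)
  structure(list(labels = labels,
                 sizes = as.integer(table(factor(labels, levels = seq_len(k)))),
                 centroids = centroids,
                 amplitude = as.numeric(amp[ord]),
                 inertia = km$tot.withinss, seed = seed,
                 dropped = sum(!keep), offsets = mat$offsets),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment: %d rows in %d clusters (sizes %s), inertia %.1f\n",
              length(x$labels), nrow(x$centroids),
              paste(x$sizes, collapse = "/"), x$inertia))
  invisible(x)
}

centroid_modes <- function(assignment) {
  apply(assignment$centroids, 1, function(cv)
    max(assignment$offsets[cv == max(cv)]))
}

# "weak" = low amplitude relative to the strongest centroid, or flat
# (max barely above mean: no distinct binding pattern)
weak_centroids <- function(assignment, weak_frac, flat_ratio) {
  cmax <- apply(assignment$centroids, 1, max)
  cmean <- rowMeans(assignment$centroids)
  cmax < weak_frac * max(cmax) | cmax < flat_ratio * cmean
}

#' Name clusters by centroid position and amplitude
#'
#' Codifies the naming convention used for downstream-binding promoter
#' factors: near-downstream clusters (centroid mode in (0, 1000] bp) are
#' numbered "1", "3", ... by descending amplitude; near-upstream clusters
#' (mode in [-1000, 0)) are "2", ...; everything else — far modes, over-TSS
#' and weak centroids (max below `weak_frac` of the strongest centroid
#' max) — is "combination" ("4").
#'
#' @param assignment A [kmeans_positional()] result.
#' @param near Distance bound (bp) separating near from far modes.
#' @param weak_frac Amplitude fraction below which a centroid is "weak".
#' @param flat_ratio Peakedness bound: a centroid whose maximum is below
#'   `flat_ratio` times its mean has no distinct binding pattern and is
#'   also "weak".
#' @return data.frame: `cluster`, `label`, `role`, `mode`, `amplitude`,
#'   `size`.
#' @export
name_clusters <- function(assignment, near = 1000, weak_frac = 0.25,
                          flat_ratio = 1.5) {
  modes <- centroid_modes(assignment)
  weak <- weak_centroids(assignment, weak_frac, flat_ratio)
  role <- ifelse(weak, "weak",
          ifelse(modes > 0 & modes <= near, "near_down",
          ifelse(modes < 0 & modes >= -near, "near_up",
          ifelse(modes > near, "far_down",
          ifelse(modes < -near, "far_up", "over_tss")))))
  label <- rep("4", length(modes))
  nd <- which(role == "near_down")
  nd <- nd[order(-assignment$amplitude[nd])]
  if (length(nd)) label[nd] <- as.character(c(1, 3, seq(5, by = 2,
    length.out = max(0, length(nd) - 2)))[seq_along(nd)])
  nu <- which(role == "near_up")
  nu <- nu[order(-assignment$amplitude[nu])]
  if (length(nu)) label[nu] <- as.character(c(2, seq(6, by = 2,
    length.out = max(0, length(nu) - 1)))[seq_along(nu)])
  data.frame(cluster = seq_along(modes), label = label, role = role,
             mode = modes, amplitude = assignment$amplitude,
             size = assignment$sizes, stringsAsFactors = FALSE)
}

#' Subcluster one cluster (the "combination" peaks)
#'
#' Re-runs K-means on the rows of a target cluster and orders the
#' subclusters by centroid character: `4.1` upstream-far, `4.2`
#' downstream-far, `4.3` over/near the TSS, `4.4` weak or patternless
#' (centroid max below `weak_frac` of the strongest subcentroid). Several
#' subcentroids in the same category are ordered by amplitude.
#'
#' @param mat The `SignalMatrix` the original assignment was built from.
#' @param assignment A [kmeans_positional()] result on `mat`.
#' @param target_cluster Cluster number to subdivide (or a vector of
#'   cluster numbers treated as one combination set).
#' @param k Number of subclusters.
#' @param seed Integer seed.
#' @param near,weak_frac,flat_ratio As in [name_clusters()].
#' @return List with `assignment` (a `ClusterAssignment` on the subset) and
#'   `naming` (data.frame: `cluster`, `sublabel`, `role`, `mode`).
#' @export
subcluster <- function(mat, assignment, target_cluster, k = 4L, seed = 1L,
                       near = 1000, weak_frac = 0.25, flat_ratio = 1.5) {
  rows <- names(assignment$labels)[assignment$labels %in% target_cluster]
  if (length(rows) < k)
    stop("target cluster has fewer rows than requested subclusters")
  sub <- signal_matrix(mat$values[rows, , drop = FALSE], mat$offsets,
                       mat$window, mat$binsize)
  sa <- kmeans_positional(sub, k, seed = seed)
  modes <- centroid_modes(sa)
  weak <- weak_centroids(sa, weak_frac, flat_ratio)
  role <- ifelse(weak, "weak",
          ifelse(modes < -near, "far_up",
          ifelse(modes > near, "far_down", "over_tss")))
  pri <- match(role, c("far_up", "far_down", "over_tss", "weak"))
  ord <- order(pri, -sa$amplitude)
  naming <- data.frame(cluster = seq_len(k)[ord],
                       sublabel = sprintf("4.%d", seq_len(k)),
                       role = role[ord], mode = modes[ord],
                       stringsAsFactors = FALSE)
  list(assignment = sa, naming = naming)
}

#' Peak-width summary
#'
#' @param peaks `GRanges` of peak calls.
#' @return List with `mean`, `median`, `n` (widths in bp).
#' @export
peak_width_stats <- function(peaks) {
  if (length(peaks) == 0L) stop("empty peak set")
  w <- width(peaks)
  list(mean = mean(w), median = median(w), n = length(w))
}

#' Genome-wide correlation between coverage tracks
#'
#' Pearson correlation of `log(1 + signal)` over fixed genome-wide bins
#' shared by all tracks. Tracks with zero variance yield `NA` entries and a
#' flag.
#'
#' @param tracks Named list of [binned_track()] objects on the same
#'   chromosome set and binsize.
#' @return List with `r` (correlation matrix) and `flagged` (names of
#'   zero-variance tracks).
#' @export
sample_correlation <- function(tracks) {
  stopifnot(length(tracks) >= 2L)
  chroms <- Reduce(intersect, lapply(tracks, function(t) names(t$values)))
  if (!length(chroms)) stop("tracks share no chromosomes")
  vecs <- lapply(tracks, function(t) {
    v <- unlist(t$values[chroms], use.names = FALSE)
    log1p(v)
  })
  nb <- min(lengths(vecs))
  m <- vapply(vecs, function(v) v[seq_len(nb)], numeric(nb))
  sds <- apply(m, 2, sd)
  flagged <- colnames(m)[sds == 0]
  r <- suppressWarnings(cor(m))
  diag(r) <- 1
  list(r = r, flagged = flagged)
}

#' Compare mean signal between two row groups
#'
#' @param mat A `SignalMatrix`.
#' @param group_a,group_b Disjoint, non-empty row-name sets.
#' @return List with `profile_a`, `profile_b` (per-bin means), `ratio`
#'   (overall mean a / mean b; `Inf` and a flag when group b is all zero).
#' @export
compare_group_signal <- function(mat, group_a, group_b) {
  stopifnot(length(group_a) > 0, length(group_b) > 0,
            !length(intersect(group_a, group_b)))
  va <- mat$values[group_a, , drop = FALSE]
  vb <- mat$values[group_b, , drop = FALSE]
  ratio <- mean(va) / mean(vb)
  list(profile_a = colMeans(va), profile_b = colMeans(vb),
       ratio = ratio, flagged = !is.finite(ratio))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between a clustering and ground truth.
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expect <- sum_a * sum_b / ch2(n)
  mx <- (sum_a + sum_b) / 2
  if (mx == expect) return(1)
  (sum_ij - expect) / (mx - expect)
}
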