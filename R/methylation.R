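#' Methylation beta values from probe intensities
#'
#' beta = M / (M + U). Probes with zero total intensity are masked (`NA`),
#' never reported as 0.
#'
#' @param M,U Non-negative methylated / unmethylated intensities (vectors
#'   or matrices of matching shape).
#' @return Numeric of the same shape, values in \[0, 1\] or `NA`.
#' @examples
#' beta_values(c(500, 0, 300), c(500, 100, 100))  # 0.5, 0, 0.75
#' @export
beta_values <- function(M, U) {
  stopifnot(all(M >= 0, na.rm = TRUE), all(U >= 0, na.rm = TRUE))
  tot <- M + U
  out <- M / tot
  out[tot == 0] <- NA_real_
  out
}

#' Mask measurements that fail detection
#'
#' Entries with detection p strictly greater than `p_cut` are masked; a
#' detection p of exactly `p_cut` is retained.
#'
#' @param values Numeric vector/matrix (e.g. betas or intensities).
#' @param detection_p Matching detection p values.
#' @param p_cut Cutoff (default 0.05).
#' @return `values` with failing entries set to `NA`.
#' @export
filter_detection <- function(values, detection_p, p_cut = 0.05) {
  stopifnot(length(values) == length(detection_p))
  values[detection_p > p_cut] <- NA
  values
}

#' Select promoter probes
#'
#' Keeps probes whose position lies between 1500 bp upstream of a TSS
#' (transcription direction) and the end of the first coding exon, for any
#' transcript. Transcripts without CDS structure are skipped and counted.
#'
#' @param probes data.frame with `chrom` and `pos` columns.
#' @param models A [transcript_models()] object.
#' @param upstream Upstream extent (bp).
#' @return The promoter subset of `probes`, with attribute
#'   `skipped_transcripts`.
#' @export
select_promoter_probes <- function(probes, models, upstream = 1500) {
  win <- promoter_probe_windows(models, upstream = upstream)
  pg <- GRanges(probes$chrom, IRanges(probes$pos, probes$pos))
  hits <- findOverlaps(pg, win)
  keep <- sort(unique(queryHits(hits)))
  out <- probes[keep, , drop = FALSE]
  attr(out, "skipped_transcripts") <- attr(win, "skipped")
  out
}

#' Classify methylation differences
#'
#' delta = beta_ko - beta_control; hypomethylated when delta < -cutoff,
#' hypermethylated when delta > +cutoff (strict inequalities: a delta of
#' exactly +/-cutoff is unchanged). Masked inputs yield `unclassified`.
#'
#' @param beta_control,beta_ko Beta values (may contain `NA`).
#' @param cutoff Absolute delta-beta cutoff (default 0.2).
#' @return Character vector: `hypomethylated` / `hypermethylated` /
#'   `unchanged` / `unclassified`.
#' @export
classify_dm <- function(beta_control, beta_ko, cutoff = 0.2) {
  d <- beta_ko - beta_control
  out <- rep("unchanged", length(d))
  out[d < -cutoff] <- "hypomethylated"
  out[d > cutoff] <- "hypermethylated"
  out[is.na(d)] <- "unclassified"
  out
}

#' Per-condition mean betas over unmasked replicates
#'
#' @param beta Matrix probes x samples (may contain `NA` from masking).
#' @param conditions Character vector, one condition label per column.
#' @return Matrix probes x conditions of row means over unmasked entries
#'   (`NaN` when every replicate of a condition is masked).
#' @export
condition_beta_means <- function(beta, conditions) {
  stopifnot(ncol(beta) == length(conditions))
  lv <- unique(conditions)
  out <- matrix(NA_real_, nrow(beta), length(lv),
                dimnames = list(rownames(beta), lv))
  for (cd in lv)
    out[, cd] <- rowMeans(beta[, conditions == cd, drop = FALSE],
                          na.rm = TRUE)
  out
}

#' Extract beta matrix and detection mask from a probe table
#'
#' The probe-table layout is `probe, chrom, pos`, then `M_<sample>`,
#' `U_<sample>`, `p_<sample>` column triples.
#'
#' @param probes Probe data.frame.
#' @param p_cut Detection-p cutoff passed to [filter_detection()].
#' @return List with `beta` (probes x samples, detection-filtered),
#'   `samples` (character vector), `n_masked` (entries removed by the
#'   detection filter).
#' @export
probe_beta_matrix <- function(probes, p_cut = 0.05) {
  mcols_ <- grep("^M_", names(probes), value = TRUE)
  samples <- sub("^M_", "", mcols_)
  beta <- sapply(samples, function(s)
    beta_values(probes[[paste0("M_", s)]], probes[[paste0("U_", s)]]))
  detp <- sapply(samples, function(s) probes[[paste0("p_", s)]])
  n_before <- sum(!is.na(beta))
  beta <- filter_detection(beta, detp, p_cut = p_cut)
  rownames(beta) <- probes$probe
  list(beta = beta, samples = samples,
       n_masked = n_before - sum(!is.na(beta)))
}
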