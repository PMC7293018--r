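#' Positional peak-mixture configuration
#'
#' Peaks are drawn from a five-component TSS-relative mixture capturing the
#' positional classes seen for downstream-binding promoter factors: near
#' modes at +240 / -240 bp, far modes at +2 kb / -2 kb, and a diffuse
#' uniform background. Per-component score scales make the downstream-near
#' component the strongest, matching the amplitude ordering used to name
#' clusters. Widths are log-normal: median ~1800 bp in ChIP-seq mode,
#' ~300 bp in ChIP-exo mode.
#'
#' @param mode `"seq"` or `"exo"` (sets the width median: 1800 vs 300 bp).
#' @param components data.frame with columns `name`, `weight`, `mean`, `sd`
#'   (`NA` mean/sd marks the diffuse uniform component), `score_meanlog`.
#' @param diffuse_range Support of the diffuse component (bp, TSS-relative).
#' @param width_median,width_sdlog Log-normal peak-width parameters;
#'   `width_median = NULL` picks 1800/300 by `mode`.
#' @param score_sdlog Log-normal spread of peak scores.
#' @return A list of class `PeakMixtureConfig`.
#' @export
peak_mixture_config <- function(mode = c("seq", "exo"),
                                components = NULL,
                                diffuse_range = c(-3000, 3000),
                                width_median = NULL,
                                width_sdlog = 0.25,
                                score_sdlog = 0.5) {
  mode <- match.arg(mode)
  if (is.null(components))
    components <- data.frame(
      name = c("down_near", "up_near", "down_far", "up_far", "diffuse"),
      weight = c(0.25, 0.15, 0.10, 0.10, 0.40),
      mean = c(240, -240, 2000, -2000, NA),
      sd = c(120, 120, 300, 300, NA),
      score_meanlog = log(c(50, 30, 20, 20, 10)),
      stringsAsFactors = FALSE)
  stopifnot(all(components$weight >= 0),
            abs(sum(components$weight) - 1) < 1e-8,
            all(is.na(components$sd) | components$sd >= 0))
  if (is.null(width_median))
    width_median <- if (mode == "seq") 1800 else 300
  structure(list(mode = mode, components = components,
                 diffuse_range = diffuse_range,
                 width_median = width_median, width_sdlog = width_sdlog,
                 score_sdlog = score_sdlog),
            class = "PeakMixtureConfig")
}

#' Generate peaks from the positional mixture, with a coverage track
#'
#' Each peak is assigned a transcript (without replacement while transcripts
#' remain, so promoters are bound at most once when `n_peaks` does not
#' exceed the gene count), a latent mixture component, a TSS-relative summit
#' offset mapped through the strand, a log-normal width and score. The
#' coverage track is the sum of triangular kernels (height = score,
#' half-width = width/2) over fixed bins. Component labels are retained for
#' truth-set evaluation. Summits falling off-chromosome are redrawn, with a
#' cap.
#'
#' @param models A [transcript_models()] object supplying TSSs.
#' @param mixture A [peak_mixture_config()] object.
#' @param n_peaks Number of peaks (>= 1).
#' @param chrom_lengths Named chromosome lengths (bp); required to bound the
#'   track and redraw out-of-range summits.
#' @param binsize Track bin width (bp).
#' @param sample_id Label stored on each peak.
#' @param seed Integer seed.
#' @param make_track Set `FALSE` to skip track accumulation.
#' @return List with `peaks` (`GRanges` with `name`, `summit`, `score`,
#'   `component`, `offset`, `transcript_id`, `gene_id`, `sample_id`),
#'   `track` (a [binned_track()] or `NULL`) and `truth` (the per-peak
#'   component assignment table).
#' @export
generate_peaks <- function(models, mixture = peak_mixture_config(),
                           n_peaks, chrom_lengths, binsize = 20L,
                           sample_id = "sim", seed = 1L,
                           make_track = TRUE) {
  stopifnot(n_peaks >= 1, inherits(mixture, "PeakMixtureConfig"))
  set.seed(seed)
  tdf <- tss_of(models)
  ix <- if (n_peaks <= nrow(tdf)) sample(nrow(tdf), n_peaks)
        else sample(nrow(tdf), n_peaks, replace = TRUE)
  anchor <- tdf[ix, , drop = FALSE]

  comp_tab <- mixture$components
  comp <- sample(nrow(comp_tab), n_peaks, replace = TRUE,
                 prob = comp_tab$weight)
  draw_offsets <- function(which_rows) {
    off <- numeric(length(which_rows))
    cc <- comp[which_rows]
    for (k in seq_len(nrow(comp_tab))) {
      sel <- cc == k
      if (!any(sel)) next
      if (is.na(comp_tab$mean[k]))
        off[sel] <- runif(sum(sel), mixture$diffuse_range[1],
                          mixture$diffuse_range[2])
      else
        off[sel] <- rnorm(sum(sel), comp_tab$mean[k], comp_tab$sd[k])
    }
    round(off)
  }
  offset <- draw_offsets(seq_len(n_peaks))
  summit <- ifelse(anchor$strand == "+", anchor$tss + offset,
                   anchor$tss - offset)
  lim <- chrom_lengths[anchor$chrom]
  bad <- which(summit < 1 | summit > lim)
  tries <- 0L
  while (length(bad)) {
    tries <- tries + 1L
    if (tries > 100L)
      stop(length(bad), " summits could not be placed inside chromosomes")
    offset[bad] <- draw_offsets(bad)
    summit[bad] <- ifelse(anchor$strand[bad] == "+",
                          anchor$tss[bad] + offset[bad],
                          anchor$tss[bad] - offset[bad])
    bad <- bad[summit[bad] < 1 | summit[bad] > lim[bad]]
  }

  w <- rlnorm(n_peaks, log(mixture$width_median), mixture$width_sdlog)
  score <- rlnorm(n_peaks, comp_tab$score_meanlog[comp], mixture$score_sdlog)
  pk_start <- pmax(1, round(summit - w / 2))
  pk_end <- pmin(lim, round(summit + w / 2))
  pk_start <- pmin(pk_start, summit)
  pk_end <- pmax(pk_end, summit)

  peaks <- GRanges(anchor$chrom, IRanges(pk_start, pk_end),
                   name = sprintf("%s_peak_%05d", sample_id, seq_len(n_peaks)),
                   summit = as.integer(summit), score = score,
                   component = comp_tab$name[comp],
                   offset = offset,
                   transcript_id = anchor$transcript_id,
                   gene_id = anchor$gene_id,
                   sample_id = sample_id)

  track <- NULL
  if (make_track) {
    vals <- lapply(chrom_lengths, function(L) numeric(ceiling(L / binsize)))
    track <- binned_track(vals, binsize)
    track <- add_peak_kernels(track, anchor$chrom, summit, score, w)
  }
  truth <- data.frame(name = peaks$name, component = comp_tab$name[comp],
                      offset = offset, transcript_id = anchor$transcript_id,
                      gene_id = anchor$gene_id, stringsAsFactors = FALSE)
  list(peaks = peaks, track = track, truth = truth)
}

#' Knockout-clone expression design
#'
#' Control plus `n_clones` independently derived double-knockout (DKO)
#' clones, each with `reps` biological replicates of negative-binomial
#' counts. Direct targets (genes with a downstream-bound promoter) are
#' scaled by `2^-direct_down_lfc` in every DKO clone; a disjoint unbound
#' set is scaled by `2^+indirect_up_lfc`; all other genes are exchangeable
#' across conditions.
#'
#' @param n_clones Number of knockout clones.
#' @param reps Replicates per condition (>= 2).
#' @param baseline_mu Mean baseline expression (counts).
#' @param baseline_sdlog Log-normal spread of per-gene baselines (0 = all
#'   genes at `baseline_mu`).
#' @param dispersion Negative-binomial dispersion (1/size).
#' @param direct_down_lfc Log2 fold-change magnitude of direct-target
#'   downregulation (a negative value models upregulation, used for
#'   re-expression/rescue designs).
#' @param indirect_up_lfc Log2 fold-change of indirect upregulation.
#' @param condition_labels Optional labels: control first, then clones.
#' @param seed Integer seed.
#' @return A list of class `ExpressionDesign`.
#' @export
expression_design <- function(n_clones = 3L, reps = 3L, baseline_mu = 500,
                              baseline_sdlog = 0.5, dispersion = 0.05,
                              direct_down_lfc = 2, indirect_up_lfc = 1,
                              condition_labels = NULL, seed = 1L) {
  stopifnot(reps >= 2, dispersion > 0, n_clones >= 1)
  if (is.null(condition_labels))
    condition_labels <- c("control", sprintf("DKO_%d", seq_len(n_clones)))
  stopifnot(length(condition_labels) == n_clones + 1L)
  structure(list(n_clones = as.integer(n_clones), reps = as.integer(reps),
                 baseline_mu = baseline_mu, baseline_sdlog = baseline_sdlog,
                 dispersion = dispersion,
                 direct_down_lfc = direct_down_lfc,
                 indirect_up_lfc = indirect_up_lfc,
                 condition_labels = condition_labels,
                 seed = as.integer(seed)),
            class = "ExpressionDesign")
}

#' Generate negative-binomial counts for the knockout design
#'
#' @param design An [expression_design()] object.
#' @param gene_ids Gene universe.
#' @param direct_genes Genes planted as direct (bound, downregulated)
#'   targets; must be within `gene_ids`.
#' @param indirect_genes Genes planted as indirect upregulated targets;
#'   disjoint from `direct_genes`.
#' @return List with `counts` (genes x samples integer matrix), `samples`
#'   (data.frame `sample`, `condition`) and `truth` (planted sets).
#' @export
generate_expression <- function(design, gene_ids, direct_genes = character(),
                                indirect_genes = character()) {
  stopifnot(inherits(design, "ExpressionDesign"),
            all(direct_genes %in% gene_ids),
            all(indirect_genes %in% gene_ids))
  if (length(intersect(direct_genes, indirect_genes)))
    stop("direct and indirect target sets must be disjoint")
  set.seed(design$seed)
  n <- length(gene_ids)
  mu0 <- if (design$baseline_sdlog > 0)
    rlnorm(n, log(design$baseline_mu), design$baseline_sdlog)
  else rep(design$baseline_mu, n)

  conds <- design$condition_labels
  samples <- data.frame(
    sample = unlist(lapply(conds, function(cd)
      sprintf("%s_r%d", cd, seq_len(design$reps)))),
    condition = rep(conds, each = design$reps),
    stringsAsFactors = FALSE)

  is_ko <- samples$condition != conds[1]
  dir_ix <- match(direct_genes, gene_ids)
  ind_ix <- match(indirect_genes, gene_ids)
  size <- 1 / design$dispersion
  counts <- matrix(0L, n, nrow(samples),
                   dimnames = list(gene_ids, samples$sample))
  for (j in seq_len(nrow(samples))) {
    mu <- mu0
    if (is_ko[j]) {
      mu[dir_ix] <- mu[dir_ix] * 2^(-design$direct_down_lfc)
      mu[ind_ix] <- mu[ind_ix] * 2^(design$indirect_up_lfc)
    }
    counts[, j] <- rnbinom(n, mu = mu, size = size)
  }
  list(counts = counts, samples = samples,
       truth = list(direct = direct_genes, indirect = indirect_genes))
}

#' Generate methylation probe intensities
#'
#' Probes are placed across promoter-probe windows (TSS-1500 bp through the
#' end of the first coding exon, transcription direction) and background
#' positions. Each probe has a baseline methylation beta; a planted subset
#' of promoter probes shifts by `planted_delta` in the knockout condition.
#' Intensities are `M = I * beta * e`, `U = I * (1 - beta) * e'` with
#' multiplicative log-normal noise, and a configured fraction of
#' probe/sample measurements is flagged with detection p > 0.05.
#'
#' @param models A [transcript_models()] object (needs CDS structure).
#' @param n_probes Total probes.
#' @param n_planted Promoter probes given the planted delta.
#' @param planted_delta Beta shift in knockout (negative = hypomethylation).
#' @param noise_sd SD of the log-normal intensity noise.
#' @param detect_fail Fraction of probe/sample cells flagged undetected.
#' @param intensity Base intensity `I`.
#' @param reps Replicates per condition.
#' @param promoter_fraction Fraction of probes placed in promoter windows.
#' @param seed Integer seed.
#' @return List with `probes` (data.frame: `probe`, `chrom`, `pos`, then
#'   `M_<sample>`, `U_<sample>`, `p_<sample>` triples), `samples`
#'   (data.frame) and `truth` (planted probe ids, per-probe window
#'   membership, baseline betas).
#' @export
generate_methylation <- function(models, n_probes = 2000L, n_planted = 100L,
                                 planted_delta = -0.3, noise_sd = 0.02,
                                 detect_fail = 0.02, intensity = 1000,
                                 reps = 3L, promoter_fraction = 0.7,
                                 seed = 1L) {
  set.seed(seed)
  win <- promoter_probe_windows(models)
  if (length(win) == 0L) stop("no transcripts with CDS structure")
  n_prom <- round(promoter_fraction * n_probes)
  n_bg <- n_probes - n_prom

  wix <- sample(length(win), n_prom, replace = TRUE)
  prom_pos <- start(win)[wix] +
    floor(runif(n_prom) * width(win)[wix])
  prom_chr <- as.character(seqnames(win))[wix]

  lens <- tapply(end(models$transcripts),
                 as.character(seqnames(models$transcripts)), max)
  bg_chr <- sample(names(lens), n_bg, replace = TRUE)
  bg_pos <- floor(runif(n_bg) * (lens[bg_chr] + 5000)) + 1L

  chrom <- c(prom_chr, bg_chr)
  pos <- as.integer(c(prom_pos, bg_pos))
  in_promoter <- rep(c(TRUE, FALSE), c(n_prom, n_bg))
  probe <- sprintf("cg%06d", seq_len(n_probes))

  beta0 <- runif(n_probes, 0.05, 0.95)
  planted <- sample(which(in_promoter & beta0 >= 0.4), n_planted)
  # nudge baselines so the shifted beta stays inside [0,1]
  beta0[planted] <- pmin(pmax(beta0[planted], pmax(0, -planted_delta) + 0.02),
                         1 - pmax(0, planted_delta) - 0.02)
  beta_ko <- beta0
  beta_ko[planted] <- pmin(pmax(beta0[planted] + planted_delta, 0), 1)

  conds <- c("control", "DKO")
  samples <- data.frame(
    sample = unlist(lapply(conds, function(cd)
      sprintf("%s_m%d", cd, seq_len(reps)))),
    condition = rep(conds, each = reps), stringsAsFactors = FALSE)

  out <- data.frame(probe = probe, chrom = chrom, pos = pos,
                    stringsAsFactors = FALSE)
  for (j in seq_len(nrow(samples))) {
    b <- if (samples$condition[j] == "DKO") beta_ko else beta0
    e1 <- exp(rnorm(n_probes, 0, noise_sd))
    e2 <- exp(rnorm(n_probes, 0, noise_sd))
    M <- round(intensity * b * e1)
    U <- round(intensity * (1 - b) * e2)
    detp <- runif(n_probes, 0, 0.04)
    fail <- runif(n_probes) < detect_fail
    detp[fail] <- runif(sum(fail), 0.06, 0.5)
    out[[paste0("M_", samples$sample[j])]] <- M
    out[[paste0("U_", samples$sample[j])]] <- U
    out[[paste0("p_", samples$sample[j])]] <- detp
  }
  list(probes = out, samples = samples,
       truth = list(planted = probe[planted], in_promoter = in_promoter,
                    beta_control = beta0, beta_ko = beta_ko))
}

#' Promoter probe windows: TSS-1500 through the first coding exon
#'
#' @param models A [transcript_models()] object.
#' @param upstream Upstream extent (bp) 5' of the TSS.
#' @return `GRanges` (one window per CDS-bearing transcript) with
#'   `transcript_id` and `gene_id`; transcripts without CDS are skipped and
#'   their count attached as attribute `skipped`.
#' @export
promoter_probe_windows <- function(models, upstream = 1500) {
  tx <- models$transcripts
  cds1 <- models$cds[models$cds$rank == 1L]
  m <- match(tx$transcript_id, cds1$transcript_id)
  skipped <- sum(is.na(m))
  keep <- !is.na(m)
  tx <- tx[keep]; m <- m[keep]
  plus <- as.character(strand(tx)) == "+"
  # first coding exon's 3'-most genomic boundary in transcription direction
  st <- ifelse(plus, tx$tss - upstream, start(cds1)[m])
  en <- ifelse(plus, end(cds1)[m], tx$tss + upstream)
  out <- GRanges(seqnames(tx), IRanges(pmax(st, 1), en), strand = strand(tx),
                 transcript_id = tx$transcript_id, gene_id = tx$gene_id)
  attr(out, "skipped") <- skipped
  out
}
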