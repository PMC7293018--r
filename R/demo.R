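#' Configuration for the end-to-end synthetic demonstration
#'
#' Problem sizes are chosen so the full pipeline runs in a few minutes on
#' one CPU while leaving every planted structure comfortably detectable:
#' 10,000 peaks over 12,000 virtual promoters for the positional analyses,
#' a sequenced two-chromosome toy genome for the motif and methylation
#' stages, and a 3-clone knockout expression design.
#'
#' @param n_peaks Peaks in the positional simulation.
#' @param n_genes Virtual genes for the positional/expression simulation.
#' @param window,binsize Signal-matrix geometry (bp).
#' @param k Clusters for the positional K-means.
#' @param n_direct,n_indirect Planted direct/indirect target genes.
#' @param n_motif_regions Randomized background regions per width class.
#' @param motif_widths Width classes (nt) for the coverage curve.
#' @param bound_window Promoter window (bp, each side) for the gene-level
#'   "bound" call feeding the bound-fraction pies.
#' @param genome A [genome_config()] for the sequenced toy genome (its seed
#'   is overridden by the run seed).
#' @param expression An [expression_design()] (seed likewise overridden).
#' @return List of class `DemoConfig`.
#' @export
demo_config <- function(n_peaks = 10000L, n_genes = 12000L,
                        window = 3000L, binsize = 20L, k = 4L,
                        n_direct = 300L, n_indirect = 300L,
                        n_motif_regions = 5000L,
                        motif_widths = c(20L, 200L, 2000L),
                        bound_window = 2500L,
                        genome = genome_config(),
                        expression = expression_design()) {
  structure(as.list(environment()), class = "DemoConfig")
}

#' Run the full synthetic analysis pipeline
#'
#' Generates data with known ground truth and pushes it through every
#' analysis stage: genome and annotation, positional peak mixture, coverage
#' track, nearest-TSS annotation, summit histogram and tag-density modes,
#' K-means clustering with naming and subclustering of the combination
#' cluster, ChIP-seq vs ChIP-exo width statistics, track correlations,
#' bound-vs-unbound group signal, motif-coverage null curves and
#' summit-window analysis, per-clone DEG calling with cross-clone consensus,
#' bound-fraction integration, re-expression rescue (responding promoters),
#' and methylation delta-beta classification. Deterministic for a given
#' seed.
#'
#' @param config A [demo_config()].
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param json Optional path: write the summary as JSON.
#' @return List with `summary` (flat named list of headline numbers) and
#'   `detail` (per-stage objects: annotations, assignments, reports,
#'   truth manifests).
#' @export
run_synthetic_demo <- function(config = demo_config(), seed = 1L,
                               json = NULL) {
  stopifnot(inherits(config, "DemoConfig"))
  seed <- as.integer(seed)
  s <- function(i) seed * 101L + i
  summary <- list(seed = seed)
  detail <- list()

  ## --- positional simulation -------------------------------------------
  virt <- simulate_transcripts(config$n_genes, seed = s(1))
  mix_seq <- peak_mixture_config("seq")
  gen <- generate_peaks(virt$models, mix_seq, config$n_peaks,
                        chrom_lengths = virt$chrom_lengths,
                        binsize = config$binsize, sample_id = "chipseq",
                        seed = s(2))
  ann <- assign_nearest_tss(gen$peaks, virt$models)
  tssdf <- tss_of(virt$models)
  anchors <- data.frame(peak = ann$peak, chrom = ann$chrom,
                        tss = tssdf$tss[match(ann$transcript_id,
                                              tssdf$transcript_id)],
                        strand = tssdf$strand[match(ann$transcript_id,
                                                    tssdf$transcript_id)],
                        stringsAsFactors = FALSE)
  mat <- build_signal_matrix(gen$track, anchors, window = config$window,
                             binsize = config$binsize, id_col = "peak")

  hist_prof <- summit_histogram(ann, window = config$window,
                                binsize = config$binsize)
  dens_prof <- tag_density_profile(mat)
  summary$summit_mode_bp <- hist_prof$primary_mode
  summary$summit_shoulder_bp <- hist_prof$shoulder
  summary$tag_density_mode_bp <- dens_prof$primary_mode
  summary$tag_density_shoulder_bp <- dens_prof$shoulder

  ## --- clustering -------------------------------------------------------
  km <- kmeans_positional(mat, config$k, seed = s(3))
  naming <- name_clusters(km)
  truth_comp <- setNames(gen$truth$component, gen$truth$name)
  localized <- names(km$labels)[truth_comp[names(km$labels)] != "diffuse"]
  summary$kmeans_ari <- adjusted_rand_index(km$labels[localized],
                                            truth_comp[localized])
  combo <- naming$cluster[naming$label == "4"]
  sub <- subcluster(mat, km, combo, k = 4L, seed = s(4))
  summary$subcluster_far_up_mode_bp <-
    sub$naming$mode[match("far_up", sub$naming$role)]
  summary$subcluster_far_down_mode_bp <-
    sub$naming$mode[match("far_down", sub$naming$role)]

  ## --- widths: ChIP-seq vs ChIP-exo ------------------------------------
  ws <- peak_width_stats(gen$peaks)
  gen_exo <- generate_peaks(virt$models, peak_mixture_config("exo"),
                            config$n_peaks, chrom_lengths = virt$chrom_lengths,
                            binsize = config$binsize, sample_id = "chipexo",
                            seed = s(5), make_track = FALSE)
  we <- peak_width_stats(gen_exo$peaks)
  summary$seq_mean_width_bp <- ws$mean
  summary$seq_median_width_bp <- ws$median
  summary$exo_mean_width_bp <- we$mean
  summary$width_reduction_factor <- ws$mean / we$mean

  ## --- track correlation ------------------------------------------------
  set.seed(s(6))
  rep2 <- gen$track
  for (chr in names(rep2$values)) {
    v <- rep2$values[[chr]]
    nz <- v > 0
    rep2$values[[chr]][nz] <- v[nz] * exp(rnorm(sum(nz), 0, 0.2))
  }
  other <- generate_peaks(virt$models, mix_seq, config$n_peaks,
                          chrom_lengths = virt$chrom_lengths,
                          binsize = config$binsize, sample_id = "other",
                          seed = s(7))
  corr <- sample_correlation(list(
    rep1 = rebin_track(gen$track, 500L),
    rep2 = rebin_track(rep2, 500L),
    other = rebin_track(other$track, 500L)))
  summary$replicate_correlation <- unname(corr$r["rep1", "rep2"])
  summary$independent_correlation <- unname(corr$r["rep1", "other"])

  ## --- bound vs unbound group signal (gene-body mark emulation) --------
  bound_genes <- unique(gen$truth$gene_id[gen$truth$component == "down_near"])
  unbound_genes <- setdiff(tssdf$gene_id, unique(gen$truth$gene_id))
  ga <- head(sort(bound_genes), 800)
  gb <- head(sort(unbound_genes), 800)
  body <- binned_track(lapply(virt$chrom_lengths,
                              function(L) numeric(ceiling(L / config$binsize))),
                       config$binsize)
  both <- tssdf[tssdf$gene_id %in% c(ga, gb), , drop = FALSE]
  sgn <- ifelse(both$strand == "+", 1, -1)
  body <- add_peak_kernels(body, both$chrom, both$tss + sgn * 1000L,
                           score = ifelse(both$gene_id %in% ga, 3, 1),
                           width = 2000L)
  bmat <- build_signal_matrix(body, data.frame(
    peak = both$gene_id, chrom = both$chrom, tss = both$tss,
    strand = both$strand), window = config$window,
    binsize = config$binsize, id_col = "peak")
  cmp <- compare_group_signal(bmat, ga, gb)
  summary$bound_vs_unbound_signal_ratio <- cmp$ratio

  ## --- sequenced toy genome: motif null --------------------------------
  gcfg <- config$genome; gcfg$seed <- s(8)
  genome <- generate_genome(gcfg)
  summary$n_cgi_promoters <- if (length(genome$cgi))
    sum(classify_cgi_promoter(genome$models, genome$cgi) == "CGI") else 0L
  motifs <- list(motif_spec("AGGCCTAG", "AGGCCTAG"),
                 motif_spec("GGCCT", "GGCCT"))
  curve <- NULL
  if (length(genome$cgi)) {
    curve <- width_coverage_curve(genome$cgi, genome$sequences, motifs,
                                  widths = config$motif_widths,
                                  n = config$n_motif_regions, seed = s(9))
    for (w in sort(config$motif_widths)) {
      for (m in c("GGCCT", "AGGCCTAG")) {
        summary[[sprintf("%s_coverage_w%d", tolower(m), w)]] <-
          curve$fraction[curve$motif == m & curve$width_class == w]
      }
    }
  }
  # uniform-composition 20-nt null, with its closed-form expectation
  set.seed(s(10))
  unif <- DNAStringSet(vapply(seq_len(config$n_motif_regions), function(i)
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""),
    character(1)))
  names(unif) <- sprintf("u%d", seq_along(unif))
  ucov <- motif_coverage(GRanges(names(unif), IRanges(1, 20)), unif,
                         motifs[[2]], set_name = "uniform_20nt")
  summary$ggcct_coverage_uniform20 <- ucov$fraction
  summary$ggcct_uniform20_closed_form <- 1 - (1 - 2 * 4^-5)^16

  # summit-window coverage with planted motif occurrences
  pk_small <- generate_peaks(genome$models, peak_mixture_config("exo"),
                             n_peaks = length(genome$models),
                             chrom_lengths = setNames(
                               rep(gcfg$chrom_length, gcfg$n_chroms),
                               names(genome$sequences)),
                             binsize = config$binsize, sample_id = "exo",
                             seed = s(11), make_track = FALSE)$peaks
  seqs <- genome$sequences
  set.seed(s(12))
  n_pk <- length(pk_small)
  # AGGCCTAG contains GGCCT, so planting the long motif in 25% of summit
  # windows and the short one in a further 15% yields ~40% short-motif and
  # ~25% long-motif coverage
  pick_agg <- sample(n_pk, round(0.25 * n_pk))
  pick_ggcct <- sample(setdiff(seq_len(n_pk), pick_agg),
                       round(0.15 * n_pk))
  win_of <- function(ix, half) GRanges(seqnames(pk_small)[ix],
    IRanges(pmax(1, pk_small$summit[ix] - half),
            pk_small$summit[ix] + half))
  pl1 <- plant_motifs(seqs, win_of(pick_ggcct, 8L), "GGCCT", seed = s(13))
  pl2 <- plant_motifs(pl1$sequences, win_of(pick_agg, 9L), "AGGCCTAG",
                      seed = s(14))
  seqs <- pl2$sequences
  chex <- chexmix_window_coverage(pk_small, seqs, motifs, flank = 10L)
  summary$summit_aggcctag_coverage <-
    chex$fraction[chex$motif == "AGGCCTAG"]
  summary$summit_ggcct_coverage <- chex$fraction[chex$motif == "GGCCT"]

  ## --- expression: per-clone DEGs, consensus, integration --------------
  ecfg <- config$expression; ecfg$seed <- s(15)
  genes <- tssdf$gene_id
  set.seed(s(16))
  direct <- sort(sample(bound_genes, config$n_direct))
  indirect <- sort(sample(unbound_genes, config$n_indirect))
  expr <- generate_expression(ecfg, genes, direct, indirect)
  ctrl <- expr$samples$sample[expr$samples$condition == "control"]
  clones <- setdiff(unique(expr$samples$condition), "control")
  degs <- lapply(clones, function(cl)
    call_degs(expr$counts, ctrl,
              expr$samples$sample[expr$samples$condition == cl]))
  names(degs) <- clones
  cons_down <- consensus_sets(degs, "down")
  cons_up <- consensus_sets(degs, "up")
  summary$down_all_clones <- unname(cons_down$sizes["all_clones"])
  summary$down_at_least_two <- unname(cons_down$sizes["at_least_two"])
  summary$up_all_clones <- unname(cons_up$sizes["all_clones"])
  summary$up_at_least_two <- unname(cons_up$sizes["at_least_two"])
  summary$deg_sensitivity <-
    length(intersect(direct, cons_down$all_clones)) / length(direct)
  summary$deg_fdr <- if (length(cons_down$all_clones))
    length(setdiff(cons_down$all_clones, direct)) /
      length(cons_down$all_clones) else 0

  paper_label <- setNames(naming$label, naming$cluster)
  peak_cluster <- paper_label[as.character(km$labels)]
  names(peak_cluster) <- names(km$labels)
  binding <- gene_level_binding(ann, window = rep(config$bound_window, 2),
                                clusters = peak_cluster)
  bf_down <- bound_fraction_by_cluster(cons_down$all_clones, binding)
  bf_up <- bound_fraction_by_cluster(cons_up$all_clones, binding)
  summary$down_bound_pct <- 100 * bf_down$bound_fraction
  summary$up_bound_pct <- 100 * bf_up$bound_fraction

  ## --- rescue / responding promoters -----------------------------------
  rcfg <- expression_design(n_clones = 1L, reps = ecfg$reps,
                            baseline_mu = ecfg$baseline_mu,
                            baseline_sdlog = ecfg$baseline_sdlog,
                            dispersion = ecfg$dispersion,
                            direct_down_lfc = -ecfg$direct_down_lfc,
                            condition_labels = c("DKO_vector", "DKO_rescue"),
                            seed = s(17))
  resc <- generate_expression(rcfg, genes, direct)
  rdeg <- call_degs(resc$counts,
                    resc$samples$sample[resc$samples$condition == "DKO_vector"],
                    resc$samples$sample[resc$samples$condition == "DKO_rescue"])
  rescued_up <- deg_genes(rdeg, "up")
  bound_down <- intersect(cons_down$all_clones, binding$gene_id)
  responders <- responding_promoters(bound_down, rescued_up)
  summary$n_bound_down <- length(bound_down)
  summary$n_rescued_up <- length(rescued_up)
  summary$n_responders <- length(responders)
  summary$responder_recovery <-
    length(intersect(responders, direct)) / length(direct)

  ## --- methylation ------------------------------------------------------
  meth <- generate_methylation(genome$models, seed = s(18))
  bm <- probe_beta_matrix(meth$probes)
  prom <- select_promoter_probes(meth$probes, genome$models)
  cb <- condition_beta_means(bm$beta, meth$samples$condition)
  cls <- classify_dm(cb[, "control"], cb[, "DKO"])
  names(cls) <- rownames(bm$beta)
  planted <- meth$truth$planted
  summary$meth_probes_total <- nrow(meth$probes)
  summary$meth_probes_promoter <- nrow(prom)
  summary$meth_masked_measurements <- bm$n_masked
  summary$meth_hypo_recovery <-
    mean(cls[planted] == "hypomethylated")
  summary$meth_false_calls <-
    sum(cls[setdiff(names(cls), planted)] != "unchanged" &
          cls[setdiff(names(cls), planted)] != "unclassified")

  detail <- list(annotations = ann, matrix_dim = dim(mat$values),
                 kmeans = km, naming = naming, subcluster = sub,
                 curve = curve, consensus = list(down = cons_down,
                                                 up = cons_up),
                 binding = binding, bound_fraction = list(down = bf_down,
                                                          up = bf_up),
                 responders = responders, truth = list(
                   peaks = gen$truth, direct = direct, indirect = indirect,
                   methylation = meth$truth))
  if (!is.null(json))
    jsonlite::write_json(summary, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  list(summary = summary, detail = detail)
}

#' Coarsen a binned track by an integer factor
#'
#' @param track A [binned_track()] object.
#' @param factor Bins to merge (e.g. 500 turns 20 bp bins into 10 kb bins).
#' @return A [binned_track()] with means over merged bins.
#' @export
rebin_track <- function(track, factor = 500L) {
  vals <- lapply(track$values, function(v) {
    n <- ceiling(length(v) / factor)
    pad <- n * factor - length(v)
    m <- matrix(c(v, numeric(pad)), nrow = factor)
    colMeans(m)
  })
  binned_track(vals, track$binsize * as.integer(factor))
}
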