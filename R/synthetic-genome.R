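#' Configuration for the synthetic toy genome
#'
#' The generator emulates the two sequence compartments that matter for
#' CpG-island promoter analysis: background DNA with genome-typical GC
#' content, and islands with elevated GC and CpG dinucleotide density placed
#' over a configurable fraction of promoters. Island composition follows a
#' first-order Markov chain whose stationary base frequencies match `gc_cgi`
#' and whose CpG observed/expected ratio is tuned to `cpg_oe_cgi`;
#' background bases are i.i.d.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param n_genes Total genes (split evenly across chromosomes).
#' @param cgi_fraction Fraction of promoters that are CpG-island class.
#' @param gc_cgi,gc_bg GC fraction inside islands / in background.
#' @param cpg_oe_cgi CpG observed/expected inside islands.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A list of class `GenomeConfig`.
#' @export
genome_config <- function(n_chroms = 2L, chrom_length = 600000L,
                          n_genes = 120L, cgi_fraction = 0.6,
                          gc_cgi = 0.65, gc_bg = 0.41, cpg_oe_cgi = 0.75,
                          seed = 1L) {
  stopifnot(gc_bg > 0, gc_cgi > gc_bg, gc_cgi < 1,
            cgi_fraction >= 0, cgi_fraction <= 1,
            n_chroms >= 1, chrom_length > 0, n_genes >= 1)
  structure(list(n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 n_genes = as.integer(n_genes),
                 cgi_fraction = cgi_fraction, gc_cgi = gc_cgi,
                 gc_bg = gc_bg, cpg_oe_cgi = cpg_oe_cgi,
                 seed = as.integer(seed)),
            class = "GenomeConfig")
}

# Maximum-entropy dinucleotide model: start from the independence joint for
# the target base frequencies, scale the CG cell by the target o/e, and run
# IPF so both marginals return to the target frequencies. The realized o/e
# is close to (slightly above) the requested one; the stationary
# distribution of the resulting transition matrix is exact.
island_transition <- function(gc, cpg_oe) {
  pi0 <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  Q <- outer(pi0, pi0)
  Q["C", "G"] <- Q["C", "G"] * cpg_oe
  for (i in 1:300) {
    Q <- Q * (pi0 / rowSums(Q))
    Q <- t(t(Q) * (pi0 / colSums(Q)))
  }
  list(P = Q / rowSums(Q), pi = pi0,
       oe = Q["C", "G"] / (pi0["C"] * pi0["G"]))
}

sample_iid_seq <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

sample_markov_seq <- function(n, model) {
  bases <- c("A", "C", "G", "T")
  out <- character(n)
  cum <- t(apply(model$P, 1, cumsum))
  u <- runif(n)
  state <- findInterval(u[1], cumsum(model$pi)) + 1L
  out[1] <- bases[state]
  for (i in 2:n) {
    state <- findInterval(u[i], cum[state, ]) + 1L
    out[i] <- bases[state]
  }
  paste(out, collapse = "")
}

# draw one gene's structure (lengths in transcription order)
random_gene_structure <- function() {
  u5 <- sample(150:300, 1)
  cds1 <- sample(200:400, 1)
  i1 <- sample(500:1500, 1)
  cds2 <- sample(300:600, 1)
  parts <- list(utr5 = u5, cds = c(cds1, cds2), introns = i1)
  if (runif(1) < 0.5) {
    parts$introns <- c(parts$introns, sample(300:800, 1))
    parts$cds <- c(parts$cds, sample(200:400, 1))
  }
  parts
}

#' Generate the synthetic genome: sequence, gene models and CpG islands
#'
#' Genes are laid out without overlap along each chromosome with randomized
#' intergenic gaps; each has a 5' UTR, at least two CDS exons and at least
#' one intron, on a random strand. A seeded fraction of promoters is
#' CpG-island class: a CpG island covering `[-500, +1500)` around the TSS
#' (transcription direction) is recorded and the underlying sequence is
#' rewritten with the island composition model.
#'
#' @param config A [genome_config()] object.
#' @return List with elements `sequences` (`DNAStringSet`), `models`
#'   (a [transcript_models()] object), `cgi` (`GRanges`), `cgi_genes`
#'   (character vector of CGI-promoter gene ids) and `config`.
#' @export
generate_genome <- function(config = genome_config()) {
  stopifnot(inherits(config, "GenomeConfig"))
  set.seed(config$seed)
  chroms <- sprintf("chrS%d", seq_len(config$n_chroms))
  per_chrom <- table(factor(rep(chroms, length.out = config$n_genes),
                            levels = chroms))

  tx_rows <- list(); utr_rows <- list(); cds_rows <- list(); int_rows <- list()
  gid <- 0L
  for (ci in seq_along(chroms)) {
    pos <- 1L
    for (g in seq_len(per_chrom[[ci]])) {
      gid <- gid + 1L
      gap <- sample(3000:6000, 1)
      st <- random_gene_structure()
      span <- st$utr5 + sum(st$cds) + sum(st$introns)
      g_start <- pos + gap
      g_end <- g_start + span - 1L
      if (g_end + 2000L > config$chrom_length)
        stop(sprintf("could not place gene %d of %d on %s: chromosome too short",
                     g, per_chrom[[ci]], chroms[ci]))
      strand <- sample(c("+", "-"), 1)
      # transcription-order breakpoints -> genomic intervals
      lens <- c(st$utr5, rbind_lens(st$cds, st$introns))
      kinds <- c("utr5", kinds_of(length(st$cds), length(st$introns)))
      offs <- cumsum(c(0L, head(lens, -1L)))
      if (strand == "+") {
        p_start <- g_start + offs
        p_end <- p_start + lens - 1L
      } else {
        p_end <- g_end - offs
        p_start <- p_end - lens + 1L
      }
      id <- sprintf("g%04d", gid)
      txid <- sprintf("t%04d", gid)
      tx_rows[[gid]] <- data.frame(chrom = chroms[ci], start = g_start,
                                   end = g_end, strand = strand,
                                   gene_id = id, transcript_id = txid)
      pick <- function(kind) which(kinds == kind)
      utr_rows[[gid]] <- data.frame(chrom = chroms[ci],
                                    start = p_start[pick("utr5")],
                                    end = p_end[pick("utr5")],
                                    strand = strand, transcript_id = txid)
      ix <- pick("cds")
      cds_rows[[gid]] <- data.frame(chrom = chroms[ci], start = p_start[ix],
                                    end = p_end[ix], strand = strand,
                                    transcript_id = txid,
                                    rank = seq_along(ix))
      ix <- pick("intron")
      int_rows[[gid]] <- data.frame(chrom = chroms[ci], start = p_start[ix],
                                    end = p_end[ix], strand = strand,
                                    transcript_id = txid,
                                    rank = seq_along(ix))
      pos <- g_end
    }
  }
  df2gr <- function(rows) {
    df <- do.call(rbind, rows)
    gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
    for (col in setdiff(names(df), c("chrom", "start", "end", "strand")))
      mcols(gr)[[col]] <- df[[col]]
    gr
  }
  models <- transcript_models(df2gr(tx_rows), utr5 = df2gr(utr_rows),
                              cds = df2gr(cds_rows), introns = df2gr(int_rows))

  # CGI promoters
  tdf <- tss_of(models)
  n_cgi <- round(config$cgi_fraction * nrow(tdf))
  cgi_ix <- if (n_cgi > 0) sort(sample(nrow(tdf), n_cgi)) else integer(0)
  cgi <- GRanges()
  if (length(cgi_ix)) {
    up <- 500L; down <- 1500L
    plus <- tdf$strand[cgi_ix] == "+"
    st <- ifelse(plus, tdf$tss[cgi_ix] - up, tdf$tss[cgi_ix] - down + 1L)
    en <- ifelse(plus, tdf$tss[cgi_ix] + down - 1L, tdf$tss[cgi_ix] + up)
    cgi <- GRanges(tdf$chrom[cgi_ix],
                   IRanges(pmax(st, 1L), pmin(en, config$chrom_length)))
    cgi <- GenomicRanges::reduce(cgi)
  }

  # sequence: i.i.d. background, Markov islands
  seqs <- vapply(chroms, function(chr)
    sample_iid_seq(config$chrom_length, config$gc_bg), character(1))
  if (length(cgi)) {
    model <- island_transition(config$gc_cgi, config$cpg_oe_cgi)
    for (i in seq_along(cgi)) {
      chr <- as.character(seqnames(cgi))[i]
      piece <- sample_markov_seq(width(cgi)[i], model)
      substr(seqs[[chr]], start(cgi)[i], end(cgi)[i]) <- piece
    }
  }
  sequences <- DNAStringSet(seqs)
  names(sequences) <- chroms

  list(sequences = sequences, models = models, cgi = cgi,
       cgi_genes = tdf$gene_id[cgi_ix], config = config)
}

rbind_lens <- function(cds, introns) {
  # interleave cds/intron lengths in transcription order: cds1 i1 cds2 i2 ...
  out <- integer(0)
  for (i in seq_along(cds)) {
    out <- c(out, cds[i])
    if (i <= length(introns)) out <- c(out, introns[i])
  }
  out
}

kinds_of <- function(n_cds, n_int) {
  out <- character(0)
  for (i in seq_len(n_cds)) {
    out <- c(out, "cds")
    if (i <= n_int) out <- c(out, "intron")
  }
  out
}

#' Place TSS-only gene models on a virtual genome
#'
#' Large positional simulations (tens of thousands of peaks) need many
#' well-separated TSSs but no sequence. This lays out minimal single-exon
#' transcript models with randomized spacing and strand.
#'
#' @param n_genes Number of genes.
#' @param spacing Mean gene-to-gene spacing (bp); jittered uniformly by
#'   +/-20%. Must comfortably exceed twice the signal-matrix window so that
#'   neighbouring promoters do not overlap.
#' @param n_chroms Number of (virtual) chromosomes.
#' @param seed Integer seed.
#' @return List with `models` (a [transcript_models()] object, structure
#'   lists empty) and `chrom_lengths` (named vector).
#' @export
simulate_transcripts <- function(n_genes, spacing = 8000, n_chroms = 1L,
                                 seed = 1L) {
  set.seed(seed)
  chroms <- sprintf("chrV%d", seq_len(n_chroms))
  per <- table(factor(rep(chroms, length.out = n_genes), levels = chroms))
  pieces <- vector("list", length(chroms))
  lens <- setNames(numeric(length(chroms)), chroms)
  k0 <- 0L
  span <- 2000L
  for (ci in seq_along(chroms)) {
    nc <- per[[ci]]
    gaps <- runif(nc, 0.8 * spacing, 1.2 * spacing)
    tss <- round(5000 + cumsum(gaps))
    strand <- sample(c("+", "-"), nc, replace = TRUE)
    st <- ifelse(strand == "+", tss, tss - span + 1L)
    ids <- k0 + seq_len(nc)
    pieces[[ci]] <- data.frame(chrom = chroms[ci], start = st,
                               end = st + span - 1L, strand = strand,
                               gene_id = sprintf("vg%05d", ids),
                               transcript_id = sprintf("vt%05d", ids),
                               stringsAsFactors = FALSE)
    lens[ci] <- max(tss) + 10000
    k0 <- k0 + nc
  }
  df <- do.call(rbind, pieces)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
                gene_id = df$gene_id, transcript_id = df$transcript_id)
  list(models = transcript_models(gr), chrom_lengths = lens)
}

#' Plant literal motif occurrences into sequences
#'
#' Inserts (overwrites) `count_per_region` non-overlapping copies of `motif`
#' at seeded random positions inside each region, returning the modified
#' sequences and a manifest of every planted site for truth-set evaluation.
#'
#' @param sequences Named `DNAStringSet` or named character vector.
#' @param regions `GRanges` of target regions (1-based closed).
#' @param motif Character string over `A`,`C`,`G`,`T`.
#' @param count_per_region Copies per region; 0 returns input unchanged.
#' @param seed Integer seed.
#' @return List with `sequences` (`DNAStringSet`) and `manifest`
#'   (data.frame: `chrom`, `start`, `end`, `motif`).
#' @export
plant_motifs <- function(sequences, regions, motif, count_per_region = 1L,
                         seed = 1L) {
  if (!grepl("^[ACGT]+$", motif)) stop("motif must be over A/C/G/T")
  set.seed(seed)
  seqs <- as.character(sequences)
  m <- nchar(motif)
  manifest <- list()
  if (count_per_region > 0) {
    for (i in seq_along(regions)) {
      chr <- as.character(seqnames(regions))[i]
      if (!chr %in% names(seqs)) stop("region on unknown sequence: ", chr)
      lo <- start(regions)[i]; hi <- end(regions)[i]
      if (hi > nchar(seqs[[chr]])) stop("region beyond sequence end: ", chr)
      L <- hi - lo + 1L
      if (L < count_per_region * m)
        stop(sprintf("region %d too small for %d copies of a %d-mer",
                     i, count_per_region, m))
      placed <- integer(0)
      tries <- 0L
      while (length(placed) < count_per_region) {
        tries <- tries + 1L
        if (tries > 1000L * count_per_region)
          stop("could not place non-overlapping motif copies in region ", i)
        cand <- lo + sample.int(L - m + 1L, 1L) - 1L
        if (!any(abs(cand - placed) < m)) placed <- c(placed, cand)
      }
      for (p in sort(placed)) {
        substr(seqs[[chr]], p, p + m - 1L) <- motif
        manifest[[length(manifest) + 1L]] <-
          data.frame(chrom = chr, start = p, end = p + m - 1L, motif = motif,
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- DNAStringSet(seqs)
  names(out) <- names(seqs)
  list(sequences = out,
       manifest = if (length(manifest)) do.call(rbind, manifest)
                  else data.frame(chrom = character(), start = integer(),
                                  end = integer(), motif = character()))
}
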