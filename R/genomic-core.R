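#' Transcript models with resolved gene structure
#'
#' Container tying together stranded transcript spans, their TSS positions,
#' 5' UTR intervals, CDS exons and introns (the latter three in transcription
#' order). All coordinates are 1-based closed genomic positions, the native
#' GRanges convention; BED-derived input is converted on read.
#'
#' @param transcripts `GRanges` with metadata columns `gene_id` and
#'   `transcript_id`; strand must be `+` or `-`.
#' @param utr5,cds,introns `GRanges` with a `transcript_id` metadata column;
#'   `cds` and `introns` additionally carry an integer `rank` giving
#'   transcription order (rank 1 = first coding exon / first intron).
#' @return An object of class `TranscriptModels` with elements `transcripts`
#'   (gains a `tss` column: `start` on `+`, `end` on `-`), `utr5`, `cds`,
#'   `introns`.
#' @examples
#' tx <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 4000), "+",
#'                              gene_id = "g1", transcript_id = "t1")
#' tm <- transcript_models(tx)
#' tss_of(tm)
#' @export
transcript_models <- function(transcripts,
                              utr5 = GRanges(),
                              cds = GRanges(),
                              introns = GRanges()) {
  stopifnot(is(transcripts, "GRanges"))
  need <- c("gene_id", "transcript_id")
  if (!all(need %in% names(mcols(transcripts))))
    stop("transcripts must carry gene_id and transcript_id metadata columns")
  strand_chr <- as.character(strand(transcripts))
  if (any(strand_chr == "*"))
    stop("transcripts must be stranded (+ or -)")
  if (anyDuplicated(transcripts$transcript_id))
    stop("duplicate transcript_id")
  mcols(transcripts)$tss <- ifelse(strand_chr == "+",
                                   start(transcripts), end(transcripts))
  for (part in list(utr5, cds, introns)) {
    if (length(part) && !"transcript_id" %in% names(mcols(part)))
      stop("structure parts need a transcript_id column")
  }
  structure(list(transcripts = transcripts, utr5 = utr5, cds = cds,
                 introns = introns),
            class = "TranscriptModels")
}

#' @export
print.TranscriptModels <- function(x, ...) {
  cat(sprintf("TranscriptModels: %d transcripts (%d genes) on %d sequence(s)\n",
              length(x$transcripts),
              length(unique(x$transcripts$gene_id)),
              length(unique(as.character(seqnames(x$transcripts))))))
  cat(sprintf("  structure: %d 5'UTR, %d CDS exon, %d intron intervals\n",
              length(x$utr5), length(x$cds), length(x$introns)))
  invisible(x)
}

#' @export
length.TranscriptModels <- function(x) length(x$transcripts)

#' TSS positions of a model set
#'
#' @param models A `TranscriptModels` object.
#' @return A data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `tss` (1-based position of the 5' end) and `strand`, ordered as in the
#'   container.
#' @export
tss_of <- function(models) {
  tx <- models$transcripts
  data.frame(transcript_id = tx$transcript_id,
             gene_id = tx$gene_id,
             chrom = as.character(seqnames(tx)),
             tss = tx$tss,
             strand = as.character(strand(tx)),
             stringsAsFactors = FALSE)
}

#' Signed TSS-relative distance of a position
#'
#' Positive distances are downstream of the TSS in the direction of
#' transcription, so a summit 240 bp into the transcribed region has distance
#' +240 on either strand. This sign convention anchors every positional
#' analysis in the package.
#'
#' @param summit Genomic position(s), 1-based.
#' @param tss TSS position(s), recycled against `summit`.
#' @param strand `"+"` or `"-"`, recycled.
#' @return Integer vector of signed distances (bp).
#' @examples
#' tss_distance(1240, 1000, "+")  # +240
#' tss_distance(4760, 5000, "-")  # +240
#' @export
tss_distance <- function(summit, tss, strand) {
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  ifelse(strand == "+", summit - tss, tss - summit)
}

#' Annotate peaks with their nearest TSS
#'
#' For each peak summit, finds the TSS minimising the absolute signed
#' distance among all transcripts on the same chromosome. Ties (a summit
#' exactly midway between two TSSs) are broken toward the lexicographically
#' smallest `transcript_id`, so output is deterministic. Peaks on
#' chromosomes without any transcript are flagged `unassigned` rather than
#' dropped.
#'
#' @param peaks `GRanges` of peak calls with a `summit` metadata column
#'   (absolute 1-based position) and optionally `score` and `name`.
#' @param models A [transcript_models()] object.
#' @param promoter_window Length-2 numeric, upstream and downstream extents
#'   (both positive, bp) of the promoter used for the promoter /
#'   non-promoter call; inclusive on both boundaries.
#' @return data.frame with one row per peak: `peak`, `chrom`, `summit`,
#'   `score`, `transcript_id`, `gene_id`, `distance`, `location_class`
#'   (`promoter`/`non-promoter`) and `unassigned`.
#' @export
assign_nearest_tss <- function(peaks, models, promoter_window = c(1000, 1000)) {
  stopifnot(is(peaks, "GRanges"), inherits(models, "TranscriptModels"))
  if (!"summit" %in% names(mcols(peaks)))
    stop("peaks must carry a 'summit' metadata column")
  tssdf <- tss_of(models)
  if (nrow(tssdf) == 0L) stop("empty transcript set")

  n <- length(peaks)
  out <- data.frame(
    peak = if (!is.null(peaks$name)) as.character(peaks$name)
           else sprintf("peak_%d", seq_len(n)),
    chrom = as.character(seqnames(peaks)),
    summit = peaks$summit,
    score = if (!is.null(peaks$score)) peaks$score else NA_real_,
    transcript_id = NA_character_, gene_id = NA_character_,
    distance = NA_real_, location_class = NA_character_,
    unassigned = FALSE, stringsAsFactors = FALSE)

  for (chr in unique(out$chrom)) {
    pk_idx <- which(out$chrom == chr)
    cand <- tssdf[tssdf$chrom == chr, , drop = FALSE]
    if (nrow(cand) == 0L) {
      out$unassigned[pk_idx] <- TRUE
      next
    }
    # order by position, then transcript_id so that findInterval ties resolve
    # reproducibly; equal-|distance| ties handled explicitly below
    cand <- cand[order(cand$tss, cand$transcript_id), , drop = FALSE]
    s <- out$summit[pk_idx]
    lo <- findInterval(s, cand$tss)          # index of rightmost tss <= s
    hi <- pmin(lo + 1L, nrow(cand))
    lo <- pmax(lo, 1L)
    d_lo <- abs(s - cand$tss[lo])
    d_hi <- abs(s - cand$tss[hi])
    pick <- ifelse(d_hi < d_lo, hi, lo)
    # exact tie between two distinct TSSs: smaller transcript_id wins
    tie <- which(d_hi == d_lo & hi != lo)
    if (length(tie)) {
      a <- cand$transcript_id[lo[tie]]; b <- cand$transcript_id[hi[tie]]
      pick[tie] <- ifelse(a <= b, lo[tie], hi[tie])
    }
    # a same-position duplicate TSS could precede the picked row
    same <- which(cand$tss[pmax(pick - 1L, 1L)] == cand$tss[pick] &
                    pick > 1L)
    if (length(same)) pick[same] <- pick[same] - 1L
    out$transcript_id[pk_idx] <- cand$transcript_id[pick]
    out$gene_id[pk_idx] <- cand$gene_id[pick]
    out$distance[pk_idx] <- tss_distance(s, cand$tss[pick], cand$strand[pick])
  }
  ok <- !out$unassigned
  out$location_class[ok] <-
    classify_peak_location(out$distance[ok], promoter_window)
  out
}

#' Promoter / non-promoter call from a signed TSS distance
#'
#' @param distance Signed TSS-relative distance(s), downstream positive.
#' @param promoter_window Length-2 positive numeric `c(upstream, downstream)`
#'   extents in bp. Boundaries are inclusive: distance -1000 with a
#'   `c(1000, 1000)` window is a promoter position.
#' @return Character vector, `"promoter"` or `"non-promoter"`.
#' @export
classify_peak_location <- function(distance, promoter_window = c(1000, 1000)) {
  stopifnot(length(promoter_window) == 2L, all(promoter_window > 0))
  ifelse(distance >= -promoter_window[1] & distance <= promoter_window[2],
         "promoter", "non-promoter")
}

#' Classify promoters as CpG-island or non-CpG-island
#'
#' A promoter is CGI-class when the window around its TSS (measured in the
#' direction of transcription) overlaps at least one base of a CpG-island
#' interval.
#'
#' @param models A [transcript_models()] object.
#' @param cgi `GRanges` of CpG-island intervals.
#' @param window Length-2 positive numeric `c(upstream, downstream)` bp.
#' @return Character vector (`"CGI"` / `"non-CGI"`), one per transcript,
#'   named by `transcript_id`.
#' @export
classify_cgi_promoter <- function(models, cgi, window = c(1000, 1000)) {
  stopifnot(inherits(models, "TranscriptModels"), is(cgi, "GRanges"))
  prom <- promoter_windows(models, window)
  hits <- findOverlaps(prom, cgi, minoverlap = 1L)
  cls <- rep("non-CGI", length(prom))
  cls[unique(queryHits(hits))] <- "CGI"
  names(cls) <- prom$transcript_id
  cls
}

#' Strand-aware promoter windows around each TSS
#'
#' @inheritParams classify_cgi_promoter
#' @return `GRanges` with `transcript_id` and `gene_id`, one window per
#'   transcript; the upstream extent points 5' of the TSS in transcription
#'   direction.
#' @export
promoter_windows <- function(models, window = c(1000, 1000)) {
  tx <- models$transcripts
  plus <- as.character(strand(tx)) == "+"
  st <- ifelse(plus, tx$tss - window[1], tx$tss - window[2])
  en <- ifelse(plus, tx$tss + window[2], tx$tss + window[1])
  GRanges(seqnames(tx), IRanges(pmax(st, 1L), en), strand = strand(tx),
          transcript_id = tx$transcript_id, gene_id = tx$gene_id)
}

#' Gene-structure class of a summit position
#'
#' Places a summit into one of `5'UTR`, `first_coding_exon`, `first_intron`,
#' `other_transcribed`, `upstream` or `intergenic` relative to a given
#' transcript. When structural annotations overlap, the first matching class
#' in the order above wins. For transcripts lacking CDS annotation the exonic
#' 5' classes collapse to `5'-exonic`.
#'
#' @param summit Genomic position(s), 1-based.
#' @param models A [transcript_models()] object.
#' @param transcript_id Transcript(s) to classify against, recycled.
#' @param upstream Extent (bp) of the `upstream` class 5' of the TSS;
#'   positions further out (or 3' of the transcript end) are `intergenic`.
#' @return Character vector of classes.
#' @export
classify_gene_region <- function(summit, models, transcript_id,
                                 upstream = 1000) {
  stopifnot(inherits(models, "TranscriptModels"))
  n <- max(length(summit), length(transcript_id))
  summit <- rep_len(summit, n)
  transcript_id <- rep_len(transcript_id, n)
  tx <- models$transcripts
  idx <- match(transcript_id, tx$transcript_id)
  if (anyNA(idx)) stop("unknown transcript_id")

  in_part <- function(part, which_rank = NULL) {
    if (length(part) == 0L) return(rep(FALSE, n))
    keep <- rep(TRUE, length(part))
    if (!is.null(which_rank) && "rank" %in% names(mcols(part)))
      keep <- part$rank == which_rank
    p <- part[keep]
    ans <- rep(FALSE, n)
    m <- match(transcript_id, p$transcript_id)  # may miss multi-part, do full
    for (i in seq_len(n)) {
      rows <- which(p$transcript_id == transcript_id[i])
      if (length(rows))
        ans[i] <- any(summit[i] >= start(p)[rows] & summit[i] <= end(p)[rows])
    }
    ans
  }

  d <- tss_distance(summit, tx$tss[idx], as.character(strand(tx))[idx])
  inside <- summit >= start(tx)[idx] & summit <= end(tx)[idx]
  has_cds <- tx$transcript_id[idx] %in% models$cds$transcript_id

  cls <- rep("intergenic", n)
  cls[d < 0 & d >= -upstream] <- "upstream"
  cls[inside] <- "other_transcribed"
  first_intron <- in_part(models$introns, which_rank = 1L)
  cls[inside & first_intron] <- "first_intron"
  first_cds <- in_part(models$cds, which_rank = 1L)
  cls[inside & first_cds] <- "first_coding_exon"
  utr <- in_part(models$utr5)
  cls[inside & utr] <- "5'UTR"
  # transcripts without CDS cannot distinguish UTR from coding 5' exon
  no_cds_5p <- inside & !has_cds & (utr | first_cds)
  cls[no_cds_5p] <- "5'-exonic"
  cls
}

#' Reduce peak annotations to gene-level binding with cluster labels
#'
#' A gene is *bound* when any of its transcripts has a peak summit within the
#' given promoter window of its TSS. When several peaks qualify, the gene
#' inherits the cluster label of its highest-scoring promoter peak
#' ("strongest cluster wins").
#'
#' @param annotations data.frame from [assign_nearest_tss()].
#' @param window Length-2 positive numeric promoter window (bp).
#' @param clusters Optional named vector mapping `peak` ids to cluster
#'   labels; genes bound only by unlabelled peaks get label `"bound"`.
#' @return data.frame with `gene_id`, `bound` (logical), `category` (cluster
#'   label or `"unbound"`), `best_peak`, `best_score`.
#' @export
gene_level_binding <- function(annotations, window = c(1000, 1000),
                               clusters = NULL) {
  ann <- annotations[!annotations$unassigned, , drop = FALSE]
  inwin <- ann$distance >= -window[1] & ann$distance <= window[2]
  ann <- ann[inwin, , drop = FALSE]
  if (nrow(ann) == 0L)
    return(data.frame(gene_id = character(), bound = logical(),
                      category = character(), best_peak = character(),
                      best_score = numeric(), stringsAsFactors = FALSE))
  ann <- ann[order(ann$gene_id, -ann$score, ann$peak), , drop = FALSE]
  best <- ann[!duplicated(ann$gene_id), , drop = FALSE]
  cat_of <- rep("bound", nrow(best))
  if (!is.null(clusters)) {
    m <- clusters[best$peak]
    cat_of <- ifelse(is.na(m), "bound", as.character(m))
  }
  data.frame(gene_id = best$gene_id, bound = TRUE, category = cat_of,
             best_peak = best$peak, best_score = best$score,
             stringsAsFactors = FALSE)
}

# 1-based closed overlap width used by small internal checks; exercised
# against an exhaustive oracle in the test-suite.
interval_overlap <- function(start1, end1, start2, end2) {
  pmax(0L, pmin(end1, end2) - pmax(start1, start2) + 1L)
}
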