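## Format readers/writers. Parsing of the standard formats is delegated to
## rtracklayer/Biostrings; the functions here fix the package's conventions
## (1-based internal coordinates, summit resolution, GENCODE-dialect GTF
## attributes) and validate what the formats themselves do not.

#' Read a BED file as GRanges
#'
#' BED 0-based half-open coordinates are converted to the 1-based closed
#' GRanges convention by the reader.
#' @param path File path.
#' @return `GRanges`.
#' @export
read_bed <- function(path) rtracklayer::import(path, format = "BED")

#' Write GRanges as BED
#' @param gr `GRanges`.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read ENCODE narrowPeak peak calls
#'
#' The 10th column is the summit offset from the (0-based) peak start; the
#' absolute 1-based summit is `bed_start + offset + 1`. A missing offset
#' (`-1`) falls back to the interval midpoint.
#'
#' @param path File path.
#' @return `GRanges` with `name`, `score`, `signalValue`, `pValue`,
#'   `qValue` and a resolved absolute `summit` column.
#' @export
read_narrowpeak <- function(path) {
  gr <- rtracklayer::import(path, format = "BED",
                            extraCols = c(signalValue = "numeric",
                                          pValue = "numeric",
                                          qValue = "numeric",
                                          peak = "integer"))
  off <- gr$peak
  mid <- floor((start(gr) + end(gr)) / 2)
  summit <- ifelse(!is.na(off) & off >= 0L, start(gr) + off, mid)
  if (any(summit < start(gr) | summit > end(gr)))
    stop("narrowPeak summit offset outside its interval")
  mcols(gr)$summit <- summit
  mcols(gr)$peak <- NULL
  gr
}

#' Write peaks as ENCODE narrowPeak
#'
#' @param peaks `GRanges` with `summit` (absolute, 1-based) and optionally
#'   `name`, `score`, `signalValue`, `pValue`, `qValue`.
#' @param path Output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  stopifnot("summit" %in% names(mcols(peaks)))
  n <- length(peaks)
  grab <- function(col, default) {
    v <- mcols(peaks)[[col]]
    if (is.null(v)) rep_len(default, n) else v
  }
  df <- data.frame(
    chrom = as.character(seqnames(peaks)),
    start = start(peaks) - 1L,                       # back to 0-based
    end = end(peaks),
    name = grab("name", "."),
    score = round(grab("score", 0)),
    strand = ".",
    signalValue = grab("signalValue", grab("score", 0)),
    pValue = grab("pValue", -1),
    qValue = grab("qValue", -1),
    peak = peaks$summit - start(peaks))              # offset from 0-based start
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GENCODE-dialect GTF
#'
#' Uses `transcript`, `exon`, `CDS` and `UTR` features; 5' UTRs are the UTR
#' intervals on the TSS side of the first CDS, introns are the gaps between
#' consecutive exons, and CDS exons/introns are ranked in transcription
#' order.
#'
#' @param path File path.
#' @return A [transcript_models()] object.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  transcript_models_from_granges(gr)
}

#' Assemble transcript models from parsed GTF records
#'
#' @param gr `GRanges` with `type`, `gene_id`, `transcript_id` columns as
#'   produced by `rtracklayer::import(format = "gtf")`.
#' @return A [transcript_models()] object.
#' @export
transcript_models_from_granges <- function(gr) {
  type <- as.character(gr$type)
  tx <- gr[type == "transcript"]
  if (length(tx) == 0L) stop("no transcript features in GTF input")
  mcols(tx) <- mcols(tx)[, c("gene_id", "transcript_id")]

  exons <- gr[type == "exon"]
  cds <- gr[type == "CDS"]
  utr <- gr[type == "UTR"]

  rank_by_tx <- function(part) {
    if (length(part) == 0L)
      return(GRanges(transcript_id = character(), rank = integer()))
    o <- order(part$transcript_id, start(part))
    part <- part[o]
    neg <- as.character(strand(part)) == "-"
    rk <- unlist(lapply(split(seq_along(part), part$transcript_id),
                        function(ix) {
                          r <- seq_along(ix)
                          if (neg[ix[1]]) rev(r) else r
                        }), use.names = FALSE)
    # split() reorders by factor level; rebuild in that order
    ix <- unlist(split(seq_along(part), part$transcript_id), use.names = FALSE)
    part <- part[ix]
    mcols(part) <- S4Vectors::DataFrame(transcript_id = part$transcript_id,
                                        rank = rk)
    part
  }

  introns_of <- function(exons) {
    pieces <- lapply(split(exons, exons$transcript_id), function(e) {
      if (length(e) < 2L) return(GRanges())
      e <- e[order(start(e))]
      gaps <- GRanges(seqnames(e)[-1],
                      IRanges(end(e)[-length(e)] + 1L, start(e)[-1] - 1L),
                      strand = strand(e)[-1])
      gaps$transcript_id <- e$transcript_id[-1]
      gaps
    })
    out <- suppressWarnings(do.call(c, unname(pieces)))
    if (is.null(out)) GRanges(transcript_id = character()) else out
  }

  tssv <- ifelse(as.character(strand(tx)) == "+", start(tx), end(tx))
  utr5 <- GRanges()
  if (length(utr) && length(cds)) {
    cds_by_tx <- split(cds, cds$transcript_id)
    keep <- vapply(seq_along(utr), function(i) {
      id <- utr$transcript_id[i]
      cc <- cds_by_tx[[id]]
      if (is.null(cc)) return(FALSE)
      if (as.character(strand(utr)[i]) == "+")
        end(utr)[i] <= min(start(cc))
      else
        start(utr)[i] >= max(end(cc))
    }, logical(1))
    utr5 <- utr[keep]
    mcols(utr5) <- S4Vectors::DataFrame(transcript_id = utr5$transcript_id)
  }

  transcript_models(tx,
                    utr5 = utr5,
                    cds = rank_by_tx(cds),
                    introns = rank_by_tx(introns_of(exons)))
}

#' Write transcript models as GENCODE-dialect GTF
#'
#' Emits `transcript`, `exon`, `CDS` and `UTR` lines (1-based closed, per
#' GTF) with `gene_id`/`transcript_id` attributes, round-trippable through
#' [read_gtf()].
#'
#' @param models A [transcript_models()] object.
#' @param path Output path.
#' @export
write_gtf <- function(models, path) {
  tx <- models$transcripts
  attr_str <- function(g, t)
    sprintf('gene_id "%s"; transcript_id "%s";', g, t)
  line <- function(chr, src, type, st, en, strand, attrs)
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chr, src, type, st, en, strand, attrs)
  lines <- character(0)
  exon_rows <- function(id) {
    # exons = union of utr5 + cds intervals, merged when contiguous
    parts <- c(models$utr5[models$utr5$transcript_id == id],
               granges_drop_mcols(models$cds[models$cds$transcript_id == id]))
    if (length(parts) == 0L) return(GRanges())
    GenomicRanges::reduce(sort(parts))
  }
  for (i in seq_along(tx)) {
    chr <- as.character(seqnames(tx))[i]
    std <- as.character(strand(tx))[i]
    at <- attr_str(tx$gene_id[i], tx$transcript_id[i])
    lines <- c(lines, line(chr, "tssanchor", "transcript",
                           start(tx)[i], end(tx)[i], std, at))
    ex <- exon_rows(tx$transcript_id[i])
    for (j in seq_along(ex))
      lines <- c(lines, line(chr, "tssanchor", "exon",
                             start(ex)[j], end(ex)[j], std, at))
    cc <- models$cds[models$cds$transcript_id == tx$transcript_id[i]]
    for (j in seq_along(cc))
      lines <- c(lines, line(chr, "tssanchor", "CDS",
                             start(cc)[j], end(cc)[j], std, at))
    uu <- models$utr5[models$utr5$transcript_id == tx$transcript_id[i]]
    for (j in seq_along(uu))
      lines <- c(lines, line(chr, "tssanchor", "UTR",
                             start(uu)[j], end(uu)[j], std, at))
  }
  writeLines(lines, path)
  invisible(path)
}

granges_drop_mcols <- function(gr) {
  mcols(gr) <- NULL
  gr
}

#' Read/write FASTA sequences
#' @param path File path.
#' @return `DNAStringSet`.
#' @export
read_fasta <- function(path) readDNAStringSet(path)

#' @rdname read_fasta
#' @param seqs Named `DNAStringSet` (or named character vector).
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read a bedGraph coverage file as a binned track
#'
#' @param path File path.
#' @param binsize Grid to rasterize onto (bp).
#' @param chrom_lengths Optional named chromosome lengths.
#' @return A [binned_track()] object.
#' @export
read_bedgraph <- function(path, binsize = 20L, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  rasterize_track(gr, binsize = binsize, chrom_lengths = chrom_lengths)
}

#' Write a binned track as bedGraph
#' @param track A [binned_track()] object.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  rtracklayer::export(track_as_granges(track), path, format = "bedGraph")
  invisible(path)
}

#' Read a counts table (genes x samples)
#'
#' First column gene id, header row of sample ids.
#' @param path File path.
#' @return Integer matrix with gene rownames.
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  if (any(m < 0)) stop("negative counts")
  m
}

#' @rdname read_counts
#' @param counts Matrix with gene rownames.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table by column name
#'
#' Tolerant reader for externally produced per-clone DEG tables: columns are
#' selected by (case-insensitive) name so the layouts of common DE tools can
#' be consumed directly.
#'
#' @param path File path (TSV or CSV by extension).
#' @param columns Named character vector mapping the package's fields
#'   (`gene`, `log2fc`, `p`, `padj`) to column names in the file; `p`/`padj`
#'   may be absent.
#' @return data.frame with columns `gene`, `log2fc` and, when present, `p`,
#'   `padj`.
#' @export
read_deg_table <- function(path,
                           columns = c(gene = "gene_id", log2fc = "logFC",
                                       p = "PValue", padj = "FDR")) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  find_col <- function(name) {
    hit <- which(tolower(names(df)) == tolower(name))
    if (length(hit)) hit[1] else NA_integer_
  }
  out <- data.frame(gene = as.character(df[[find_col_or_stop(df, columns["gene"])]]),
                    stringsAsFactors = FALSE)
  fc <- find_col(columns[["log2fc"]])
  if (is.na(fc)) stop("log2 fold-change column '", columns[["log2fc"]],
                      "' not found in ", path)
  out$log2fc <- as.numeric(df[[fc]])
  for (f in c("p", "padj")) {
    if (!f %in% names(columns)) next
    ix <- find_col(columns[[f]])
    if (!is.na(ix)) out[[f]] <- as.numeric(df[[ix]])
  }
  out
}

find_col_or_stop <- function(df, name) {
  hit <- which(tolower(names(df)) == tolower(name))
  if (!length(hit)) stop("column '", name, "' not found")
  hit[1]
}

#' Write a generic data.frame as TSV
#' @param df data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
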