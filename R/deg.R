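#' Call differentially expressed genes between two groups
#'
#' Plumbing-grade differential expression for synthetic count data: library
#' sizes are normalized by the median-of-ratios method, expression is
#' log2(CPM + 0.5), and per-gene tests are either a variance-moderated t
#' (limma-trend; the default, which keeps power at the small replicate
#' numbers typical of clone designs) or a plain Welch t. P-values are
#' Benjamini-Hochberg adjusted. A gene is a DEG when adjusted p < `alpha`
#' AND the normalized-mean fold change exceeds `fc_threshold` (strict
#' inequality, applied to the ratio of normalized group means, not a
#' shrunken estimate).
#'
#' @param counts Integer matrix, genes x samples, with dimnames.
#' @param group_a,group_b Sample (column) names of the two groups; `a` is
#'   the reference (control), so fold changes are b/a.
#' @param fc_threshold Fold-change threshold (> 1); 1.5 matches the common
#'   "absolute fold change > 1.5" convention.
#' @param alpha Adjusted-p cutoff.
#' @param method `"moderated"` or `"welch"`.
#' @return A `DEGTable` data.frame: `gene`, `mean_a`, `mean_b` (normalized),
#'   `log2fc`, `p`, `padj`, `direction` (`up`/`down`/`unchanged`).
#' @export
call_degs <- function(counts, group_a, group_b, fc_threshold = 1.5,
                      alpha = 0.05, method = c("moderated", "welch")) {
  method <- match.arg(method)
  stopifnot(length(group_a) >= 2, length(group_b) >= 2,
            all(c(group_a, group_b) %in% colnames(counts)),
            all(counts >= 0), fc_threshold > 1)
  m <- counts[, c(group_a, group_b), drop = FALSE]
  lib <- colSums(m)
  if (any(lib == 0)) {
    warning("dropping ", sum(lib == 0), " sample(s) with zero library size")
    keep <- lib > 0
    group_a <- intersect(group_a, colnames(m)[keep])
    group_b <- intersect(group_b, colnames(m)[keep])
    m <- m[, keep, drop = FALSE]
    lib <- lib[keep]
  }
  sf <- median_of_ratios(m)
  norm <- sweep(m, 2, sf, "/")
  eff_lib <- lib / sf
  logcpm <- log2(t(t(m + 0.5) / (eff_lib + 1)) * 1e6)

  ia <- colnames(m) %in% group_a
  ib <- colnames(m) %in% group_b
  mean_a <- rowMeans(norm[, ia, drop = FALSE])
  mean_b <- rowMeans(norm[, ib, drop = FALSE])
  fc <- (mean_b + 0.5) / (mean_a + 0.5)
  log2fc <- log2(fc)

  if (method == "moderated") {
    design <- cbind(intercept = 1, groupb = as.numeric(ib))
    fit <- limma::lmFit(logcpm, design)
    fit <- limma::eBayes(fit, trend = TRUE)
    p <- fit$p.value[, "groupb"]
  } else {
    p <- apply(logcpm, 1, function(x) {
      a <- x[ia]; b <- x[ib]
      if (sd(a) == 0 && sd(b) == 0) return(if (mean(a) == mean(b)) 1 else 0)
      tryCatch(stats::t.test(b, a)$p.value, error = function(e) 1)
    })
  }
  padj <- p.adjust(p, method = "BH")
  direction <- rep("unchanged", nrow(m))
  sig <- padj < alpha
  direction[sig & fc > fc_threshold] <- "up"
  direction[sig & fc < 1 / fc_threshold] <- "down"
  out <- data.frame(gene = rownames(m), mean_a = mean_a, mean_b = mean_b,
                    log2fc = log2fc, p = p, padj = padj,
                    direction = direction, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("DEGTable", class(out))
  out
}

# DESeq-style size factors; genes with a zero anywhere are excluded from
# the reference geometric mean. Falls back to library-size scaling when too
# few all-positive genes exist.
median_of_ratios <- function(m) {
  pos <- rowSums(m == 0) == 0
  if (sum(pos) < 10) {
    lib <- colSums(m)
    return(lib / mean(lib))
  }
  lm_ <- log(m[pos, , drop = FALSE])
  ref <- rowMeans(lm_)
  sf <- apply(lm_, 2, function(x) exp(median(x - ref)))
  sf / exp(mean(log(sf)))
}

#' Direction-specific gene lists from a DEG table
#' @param deg A `DEGTable`.
#' @param direction `"up"` or `"down"`.
#' @return Character vector of gene ids.
#' @export
deg_genes <- function(deg, direction = c("down", "up")) {
  direction <- match.arg(direction)
  deg$gene[deg$direction == direction]
}

#' Cross-clone consensus sets
#'
#' Exact set operations over per-clone DEG lists: genes called in *all*
#' clones and genes called in *at least two*. Using independently derived
#' clones this way suppresses clone-specific noise: under exchangeable null
#' data the all-clones set shrinks like `n_genes * FPR^n_clones`.
#'
#' @param clone_lists Named list, one element per clone: either a character
#'   vector of gene ids or a `DEGTable` (then `direction` selects genes).
#' @param direction Used when elements are `DEGTable`s.
#' @param universe Optional gene universe; when tables with differing
#'   universes are supplied, membership is restricted to the shared
#'   universe with a warning.
#' @return A `ConsensusSets` list: `direction`, `n_clones`, `all_clones`,
#'   `at_least_two`, `union`, `sizes` (named vector).
#' @export
consensus_sets <- function(clone_lists, direction = c("down", "up"),
                           universe = NULL) {
  direction <- match.arg(direction)
  stopifnot(length(clone_lists) >= 2L)
  is_tab <- vapply(clone_lists, inherits, logical(1), "DEGTable")
  if (any(is_tab)) {
    universes <- lapply(clone_lists[is_tab], function(t) t$gene)
    shared <- Reduce(intersect, universes)
    if (any(lengths(universes) != length(shared))) {
      warning("clone tables have mismatched gene universes; ",
              "intersecting on the shared universe")
      if (is.null(universe)) universe <- shared
    }
  }
  sets <- lapply(clone_lists, function(x) {
    g <- if (inherits(x, "DEGTable")) deg_genes(x, direction) else
      as.character(x)
    if (!is.null(universe)) g <- intersect(g, universe)
    unique(g)
  })
  all_genes <- unique(unlist(sets))
  hits <- vapply(sets, function(s) all_genes %in% s,
                 logical(length(all_genes)))
  if (length(all_genes) == 1L) hits <- matrix(hits, nrow = 1L)
  k <- rowSums(hits)
  out <- list(direction = direction, n_clones = length(sets),
              all_clones = sort(all_genes[k == length(sets)]),
              at_least_two = sort(all_genes[k >= 2L]),
              union = sort(all_genes))
  out$sizes <- c(all_clones = length(out$all_clones),
                 at_least_two = length(out$at_least_two),
                 union = length(out$union))
  class(out) <- "ConsensusSets"
  out
}

#' @export
print.ConsensusSets <- function(x, ...) {
  cat(sprintf("ConsensusSets (%s, %d clones): all=%d, >=2=%d, union=%d\n",
              x$direction, x$n_clones, x$sizes["all_clones"],
              x$sizes["at_least_two"], x$sizes["union"]))
  invisible(x)
}

#' Bound fraction of a gene set, broken down by positional cluster
#'
#' @param genes Non-empty character vector (e.g. a consensus DEG set).
#' @param binding data.frame from [gene_level_binding()] (`gene_id`,
#'   `category`). Genes absent from the table count as unbound and their
#'   number is reported.
#' @return A `BoundFractionReport` list: `set_size`, `bound_fraction`,
#'   `fractions` (named, per category plus `unbound`), `missing` (genes not
#'   in the binding table).
#' @export
bound_fraction_by_cluster <- function(genes, binding) {
  if (length(genes) == 0L) stop("empty gene set")
  genes <- unique(genes)
  cat_of <- setNames(binding$category, binding$gene_id)[genes]
  missing <- sum(is.na(cat_of))
  cat_of[is.na(cat_of)] <- "unbound"
  tab <- table(cat_of)
  fr <- as.numeric(tab) / length(genes)
  names(fr) <- names(tab)
  structure(list(set_size = length(genes),
                 bound_fraction = 1 - sum(fr[names(fr) == "unbound"]),
                 fractions = fr, missing = missing),
            class = "BoundFractionReport")
}

#' @export
print.BoundFractionReport <- function(x, ...) {
  cat(sprintf("BoundFractionReport: n=%d, bound %.1f%% (%s)\n",
              x$set_size, 100 * x$bound_fraction,
              paste(sprintf("%s %.1f%%", names(x$fractions),
                            100 * x$fractions), collapse = ", ")))
  invisible(x)
}

#' Responding promoters: bound-and-down genes rescued by re-expression
#'
#' The exact intersection of the genes that are bound in wild-type cells
#' and consistently downregulated in the knockouts with the genes whose
#' expression rises again when the factor is re-introduced.
#'
#' @param bound_down,rescued_up Character vectors of gene ids.
#' @return Sorted character vector (the responders).
#' @export
responding_promoters <- function(bound_down, rescued_up) {
  sort(intersect(bound_down, rescued_up))
}
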