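# Per-sample immune abundance (marker-mean), pathway enrichment (ssGSEA),
# TCR repertoire diversity, and group-wise differential abundance.

#' Marker-gene immune abundance scores
#'
#' For each cell population, the score of a sample is the arithmetic mean of
#' the log2 expression of the population's marker genes present in the
#' matrix (MCP-counter-style absolute abundance scoring). Sets with no
#' marker present are dropped with a warning.
#'
#' @param expr an [expression_matrix()].
#' @param markers a [gene_set_collection()] of cell-type marker sets.
#' @return numeric feature x sample matrix with attribute `method =
#'   "marker_mean"`.
#' @export
marker_abundance_scores <- function(expr, markers) {
  present <- lapply(markers, function(g) intersect(g, rownames(expr)))
  keep <- lengths(present) > 0L
  if (!any(keep)) {
    abort_icb("no marker set has any gene present in the expression matrix",
              "icb_validation_error")
  }
  if (any(!keep)) {
    warn_icb(sprintf("marker set(s) with no genes present dropped: %s",
                     paste(names(markers)[!keep], collapse = ", ")))
  }
  present <- present[keep]
  scores <- t(vapply(present, function(g) {
    colMeans(expr[g, , drop = FALSE])
  }, numeric(ncol(expr))))
  rownames(scores) <- names(present)
  colnames(scores) <- colnames(expr)
  attr(scores, "method") <- "marker_mean"
  scores
}

# Single-sample enrichment for one sample's expression vector.
# ranks: ascending ranks (ties averaged), so the highest-expressed gene has
# rank N; weights |rank|^alpha emphasise high expression.
.ssgsea_sample <- function(ranks, in_set, alpha) {
  n <- length(ranks)
  ord <- order(ranks, decreasing = TRUE)
  ind <- in_set[ord]
  w <- abs(ranks[ord])^alpha
  w[!ind] <- 0
  ecdf_in <- cumsum(w) / sum(w)
  ecdf_out <- cumsum(!ind) / (n - sum(in_set))
  sum(ecdf_in - ecdf_out)
}

#' Single-sample gene-set enrichment (ssGSEA) scores
#'
#' Per sample, genes are ranked by expression (ties averaged) and each
#' pathway's enrichment is the sum over the descending-rank walk of the
#' difference between the weighted in-set ECDF (weights `rank^alpha`) and
#' the unweighted out-of-set ECDF. Scores depend only on within-sample
#' ranks, so they are invariant under strictly monotone transforms of a
#' sample's values. With `normalize = TRUE` all scores are divided by the
#' global max - min of the score matrix.
#'
#' @param expr an [expression_matrix()] (no NA values).
#' @param pathways a [gene_set_collection()].
#' @param alpha rank-weight exponent (default 0.25, the common projection
#'   default).
#' @param normalize divide by global score range.
#' @return numeric pathway x sample matrix with attribute `method = "ssgsea"`.
#' @export
ssgsea_scores <- function(expr, pathways, alpha = 0.25, normalize = TRUE) {
  if (anyNA(expr)) {
    abort_icb("ssGSEA requires a complete (no-NA) expression matrix",
              "icb_validation_error")
  }
  genes <- rownames(expr)
  present <- lapply(pathways, function(g) intersect(g, genes))
  keep <- lengths(present) >= 2L
  if (!any(keep)) {
    abort_icb("no pathway has >= 2 genes present in the expression matrix",
              "icb_validation_error")
  }
  if (any(!keep)) {
    warn_icb(sprintf("pathway(s) with < 2 genes present dropped: %s",
                     paste(names(pathways)[!keep], collapse = ", ")))
  }
  present <- present[keep]
  full <- vapply(present, function(g) length(g) == length(genes), logical(1L))
  if (any(full)) {
    abort_icb(sprintf("pathway covers every gene (empty complement): %s",
                      paste(names(present)[full], collapse = ", ")),
              "icb_validation_error")
  }
  ranks <- apply(expr, 2L, rank, ties.method = "average")
  scores <- matrix(NA_real_, length(present), ncol(expr),
                   dimnames = list(names(present), colnames(expr)))
  for (i in seq_along(present)) {
    in_set <- genes %in% present[[i]]
    scores[i, ] <- apply(ranks, 2L, .ssgsea_sample, in_set = in_set,
                         alpha = alpha)
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  attr(scores, "method") <- "ssgsea"
  scores
}

#' TCR repertoire richness and Shannon diversity
#'
#' @param clones integer clonotype x sample matrix of counts.
#' @param bits if `TRUE` report entropy in bits (log2); default nats
#'   (natural log).
#' @return data.frame (sample_id, richness, shannon); all-zero samples get
#'   NA with a warning.
#' @export
tcr_diversity <- function(clones, bits = FALSE) {
  if (any(clones < 0, na.rm = TRUE)) {
    abort_icb("clonotype counts must be non-negative", "icb_validation_error")
  }
  logf <- if (bits) log2 else log
  res <- apply(clones, 2L, function(v) {
    v <- v[!is.na(v) & v > 0]
    if (!length(v)) return(c(richness = NA_real_, shannon = NA_real_))
    p <- v / sum(v)
    c(richness = length(v), shannon = -sum(p * logf(p)))
  })
  if (anyNA(res)) warn_icb("sample(s) with all-zero clonotype counts: NA diversity")
  data.frame(sample_id = colnames(clones), richness = res["richness", ],
             shannon = res["shannon", ], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Group-wise differential abundance of score features
#'
#' Per feature, a two-sided Wilcoxon rank-sum test between the two contrast
#' groups (exact when both groups have <= 25 samples and no ties, otherwise
#' the normal approximation with tie and continuity correction), a
#' log2 fold change computed as the difference of group means (scores are
#' log2-scale), and Benjamini-Hochberg q-values across features.
#'
#' @param scores feature x sample score matrix.
#' @param groups named character vector of group labels (names = sample ids).
#' @param contrast length-2 character vector `c(A, B)`; fold change is A - B.
#' @param exact passed to [stats::wilcox.test()]; `NULL` uses the rule above.
#' @return data.frame (feature, log2_fc, p, q, n_a, n_b).
#' @export
differential_abundance <- function(scores, groups, contrast, exact = NULL) {
  stopifnot(length(contrast) == 2L)
  if (!all(contrast %in% groups)) {
    abort_icb(sprintf("contrast group absent from labels: %s",
                      paste(setdiff(contrast, groups), collapse = ", ")),
              "icb_validation_error")
  }
  sa <- intersect(colnames(scores), names(groups)[groups == contrast[1L]])
  sb <- intersect(colnames(scores), names(groups)[groups == contrast[2L]])
  if (length(sa) < 3L || length(sb) < 3L) {
    abort_icb("both contrast groups need >= 3 scored samples",
              "icb_validation_error")
  }
  res <- lapply(rownames(scores), function(f) {
    a <- scores[f, sa]; b <- scores[f, sb]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 3L || length(b) < 3L) {
      return(data.frame(feature = f, log2_fc = NA_real_, p = NA_real_,
                        n_a = length(a), n_b = length(b)))
    }
    ex <- if (is.null(exact)) (length(a) <= 25L && length(b) <= 25L) else exact
    p <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided", exact = ex,
                         correct = TRUE)$p.value
    )
    data.frame(feature = f, log2_fc = mean(a) - mean(b), p = p,
               n_a = length(a), n_b = length(b))
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out[, c("feature", "log2_fc", "p", "q", "n_a", "n_b")]
}
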