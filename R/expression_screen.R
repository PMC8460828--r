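# Differential expression of curated gene lists and Spearman screening for
# candidate targets anti-correlated with CDKN2A/MTAP.

#' Benjamini-Hochberg q-values
#'
#' Step-up BH with enforced monotonicity. NA p-values are excluded from the
#' family size m and returned as NA.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values (same length, NAs preserved).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort_icb("p-values must lie in [0, 1]", "icb_validation_error")
  }
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Differential expression screen over a curated gene list
#'
#' Per gene: group means are taken on the linear scale (`2^x - 1` of the
#' log2 values), the fold change is the ratio of means with a pseudocount,
#' reported with the sign convention that ratios below 1 become `-1/ratio`
#' (so `|signed_fc| >= 1` always); two-sided Wilcoxon rank-sum p-values and
#' BH q-values are computed over the tested list only. A gene passes when
#' `|signed_fc| >= fc_threshold` and `q < q_threshold`.
#'
#' @param expr an [expression_matrix()] (log2 scale).
#' @param groups named character vector of group labels.
#' @param gene_list a [gene_set_collection()] or character vector; the union
#'   of its members intersected with the matrix defines the tested family.
#' @param contrast length-2 vector `c(A, B)`; fold change is A over B.
#' @param fc_threshold,q_threshold pass thresholds (defaults 1.2 and 0.05).
#' @param fc_scale `"linear"` (ratio of de-logged means, default) or
#'   `"log"` (fold change `2^(difference of log2 means)`).
#' @param exact passed to [stats::wilcox.test()]; `NULL` = exact for small
#'   tie-free groups.
#' @return data.frame (gene, signed_fc, p, q, passes, n_a, n_b);
#'   zero-variance genes get NA p and are excluded from the BH family.
#' @export
deg_screen <- function(expr, groups, gene_list, contrast,
                       fc_threshold = 1.2, q_threshold = 0.05,
                       fc_scale = c("linear", "log"), exact = NULL) {
  fc_scale <- match.arg(fc_scale)
  stopifnot(length(contrast) == 2L)
  genes <- if (inherits(gene_list, "gene_sets")) unique(unlist(gene_list)) else unique(gene_list)
  genes <- intersect(genes, rownames(expr))
  if (!length(genes)) {
    abort_icb("no listed gene present in the expression matrix",
              "icb_validation_error")
  }
  sa <- intersect(colnames(expr), names(groups)[groups == contrast[1L]])
  sb <- intersect(colnames(expr), names(groups)[groups == contrast[2L]])
  if (length(sa) < 3L || length(sb) < 3L) {
    abort_icb("both groups need >= 3 samples", "icb_validation_error")
  }
  eps <- 1e-9
  rows <- lapply(genes, function(g) {
    a <- expr[g, sa]; b <- expr[g, sb]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (fc_scale == "linear") {
      r <- (mean(2^a - 1) + eps) / (mean(2^b - 1) + eps)
    } else {
      r <- 2^(mean(a) - mean(b))
    }
    signed_fc <- if (r >= 1) r else -1 / r
    if (stats::var(c(a, b)) == 0) {
      p <- NA_real_
    } else {
      ex <- if (is.null(exact)) (length(a) <= 25L && length(b) <= 25L) else exact
      p <- suppressWarnings(
        stats::wilcox.test(a, b, alternative = "two.sided", exact = ex)$p.value
      )
    }
    data.frame(gene = g, signed_fc = signed_fc, p = p,
               n_a = length(a), n_b = length(b), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$passes <- !is.na(out$q) & abs(out$signed_fc) >= fc_threshold &
    out$q < q_threshold
  out[, c("gene", "signed_fc", "p", "q", "passes", "n_a", "n_b")]
}

# Spearman rho with mean-rank tie handling and the t approximation for p.
.spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(c(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x, ties.method = "average"),
                    rank(y, ties.method = "average"))
  if (abs(rho) >= 1) return(c(rho = rho, p = 0, n = n))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}

#' Spearman screen for targets anti-correlated with anchor genes
#'
#' For every listed gene and each anchor gene (typically CDKN2A and MTAP),
#' computes Spearman's rho (mean-rank ties), a p-value from the t
#' approximation, BH q-values per anchor over the tested list, and a tier:
#' `strong` (rho < -0.4), `moderate` (rho < -0.2), else `none`.
#'
#' @param expr an [expression_matrix()].
#' @param anchor_genes character vector of anchor gene ids.
#' @param gene_list a [gene_set_collection()] or character vector.
#' @return data.frame (gene, anchor, rho, p, q, n, tier).
#' @export
spearman_target_screen <- function(expr, anchor_genes, gene_list) {
  miss <- setdiff(anchor_genes, rownames(expr))
  if (length(miss)) {
    abort_icb(sprintf("anchor gene absent: %s", paste(miss, collapse = ", ")),
              "icb_validation_error")
  }
  if (ncol(expr) < 10L) {
    abort_icb("Spearman screen needs >= 10 samples", "icb_validation_error")
  }
  genes <- if (inherits(gene_list, "gene_sets")) unique(unlist(gene_list)) else unique(gene_list)
  genes <- intersect(genes, rownames(expr))
  if (!length(genes)) {
    abort_icb("no listed gene present in the expression matrix",
              "icb_validation_error")
  }
  out <- do.call(rbind, lapply(anchor_genes, function(anc) {
    res <- t(vapply(genes, function(g) .spearman(expr[g, ], expr[anc, ]),
                    numeric(3L)))
    data.frame(gene = genes, anchor = anc, rho = res[, "rho"],
               p = res[, "p"], q = bh_adjust(res[, "p"]), n = res[, "n"],
               stringsAsFactors = FALSE)
  }))
  out$tier <- ifelse(is.na(out$rho), NA_character_,
                     ifelse(out$rho < -0.4, "strong",
                            ifelse(out$rho < -0.2, "moderate", "none")))
  rownames(out) <- NULL
  out
}
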