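# 9p21.3 genotyping: thresholded copy calls -> gene copy states -> cohort
# stratification labels, plus the expression surrogate used when genomic
# calls are unavailable.

.copy_states <- c("HD", "LOH", "WT", "GAIN")

#' Map a thresholded copy call to a gene copy state
#'
#' -2 = homozygous deletion (HD), -1 = hemizygous loss (LOH), 0 = diploid
#' wild type (WT), +1/+2 = copy gain (GAIN).
#'
#' @param call integer vector of calls in -2..+2.
#' @return character vector of states.
#' @export
classify_gene_call <- function(call) {
  if (any(is.na(call) | call != round(call) | call < -2 | call > 2)) {
    bad <- call[is.na(call) | call != round(call) | call < -2 | call > 2][1L]
    abort_icb(sprintf("copy call out of range {-2..+2}: %s", format(bad)),
              "icb_validation_error")
  }
  c("HD", "LOH", "WT", "GAIN", "GAIN")[as.integer(call) + 3L]
}

#' Assign a 9p21 group from CDKN2A and MTAP copy states
#'
#' HD of either gene gives LOSS; LOH at both gives LOH; WT at both gives WT;
#' every other combination (single-locus LOH, any gain) is OTHER and is
#' excluded from WT-vs-LOSS contrasts downstream.
#'
#' @param cdkn2a,mtap copy states ("HD", "LOH", "WT", "GAIN").
#' @return character vector of groups ("WT", "LOH", "LOSS", "OTHER").
#' @export
assign_9p21_group <- function(cdkn2a, mtap) {
  ok <- cdkn2a %in% .copy_states & mtap %in% .copy_states
  if (!all(ok)) {
    abort_icb("copy states must be one of HD, LOH, WT, GAIN", "icb_validation_error")
  }
  out <- rep("OTHER", length(cdkn2a))
  out[cdkn2a == "HD" | mtap == "HD"] <- "LOSS"
  out[cdkn2a == "LOH" & mtap == "LOH"] <- "LOH"
  out[cdkn2a == "WT" & mtap == "WT"] <- "WT"
  out
}

#' Genotype a cohort's 9p21 status from gene-level copy calls
#'
#' @param calls a [copy_call_table()].
#' @param cdkn2a,mtap gene ids used for the two 9p21 loci.
#' @param exclude optional sample ids to drop (e.g. tumors with truncating
#'   CDKN2A mutations identified upstream).
#' @return data.frame (sample_id, group, basis); samples missing a call at
#'   either locus are dropped with a warning.
#' @export
genotype_9p21 <- function(calls, cdkn2a = "CDKN2A", mtap = "MTAP", exclude = NULL) {
  stopifnot(inherits(calls, "copy_calls"))
  a <- calls[calls$gene_id == cdkn2a, c("sample_id", "call")]
  b <- calls[calls$gene_id == mtap, c("sample_id", "call")]
  m <- merge(a, b, by = "sample_id", suffixes = c("_cdkn2a", "_mtap"))
  all_samples <- unique(calls$sample_id)
  missing <- setdiff(all_samples, m$sample_id)
  if (length(missing)) {
    warn_icb(sprintf("%d sample(s) missing a call at %s or %s; excluded",
                     length(missing), cdkn2a, mtap))
  }
  if (!is.null(exclude)) m <- m[!(m$sample_id %in% exclude), , drop = FALSE]
  data.frame(
    sample_id = m$sample_id,
    group = assign_9p21_group(classify_gene_call(m$call_cdkn2a),
                              classify_gene_call(m$call_mtap)),
    basis = "genomic",
    stringsAsFactors = FALSE
  )
}

#' Expression surrogate for 9p21 status (hi_hi / lo_lo / mixed)
#'
#' Samples with both CDKN2A and MTAP expression strictly above their
#' within-cohort medians are hi_hi; strictly below both medians, lo_lo;
#' anything else (including ties at a median) is mixed. Medians are taken
#' over all non-NA samples of the supplied cohort, so the labels are
#' rank-based and invariant under monotone transforms of the expression
#' values.
#'
#' @param expr an [expression_matrix()].
#' @param genes length-2 character vector of gene ids (CDKN2A, MTAP).
#' @return data.frame (sample_id, label, basis).
#' @export
surrogate_from_expression <- function(expr, genes = c("CDKN2A", "MTAP")) {
  stopifnot(length(genes) == 2L)
  miss <- setdiff(genes, rownames(expr))
  if (length(miss)) {
    abort_icb(sprintf("gene absent from expression matrix: %s",
                      paste(miss, collapse = ", ")),
              "icb_validation_error")
  }
  if (ncol(expr) < 4L) {
    abort_icb("surrogate labelling needs >= 4 samples", "icb_validation_error")
  }
  x <- expr[genes[1L], ]
  y <- expr[genes[2L], ]
  mx <- stats::median(x, na.rm = TRUE)
  my <- stats::median(y, na.rm = TRUE)
  lab <- rep("mixed", ncol(expr))
  lab[!is.na(x) & !is.na(y) & x > mx & y > my] <- "hi_hi"
  lab[!is.na(x) & !is.na(y) & x < mx & y < my] <- "lo_lo"
  data.frame(sample_id = colnames(expr), label = lab, basis = "surrogate",
             stringsAsFactors = FALSE)
}

#' Stratify a gene's expression into quartiles
#'
#' Samples are ranked ascending (ties get their mean rank) and cut at the
#' 25/50/75 rank percentiles; Q1 is the lowest-expression quartile. With all
#' values tied the mean rank sits just above the 50th percentile, so every
#' sample lands in Q3 (deterministic degenerate output).
#'
#' @param expr an [expression_matrix()].
#' @param gene gene id.
#' @return data.frame (sample_id, gene_id, quartile); NA-expression samples
#'   get NA quartile.
#' @export
quartile_stratify <- function(expr, gene) {
  if (!gene %in% rownames(expr)) {
    abort_icb(sprintf("gene absent from expression matrix: %s", gene),
              "icb_validation_error")
  }
  x <- expr[gene, ]
  ok <- !is.na(x)
  if (sum(ok) < 4L) {
    abort_icb("quartile stratification needs >= 4 non-NA samples",
              "icb_validation_error")
  }
  n <- sum(ok)
  r <- rank(x[ok], ties.method = "average")
  fr <- r / n
  q <- rep(NA_character_, length(x))
  q[ok] <- c("Q1", "Q2", "Q3", "Q4")[findInterval(fr, c(0, 0.25, 0.5, 0.75),
                                                  left.open = TRUE)]
  data.frame(sample_id = colnames(expr), gene_id = gene, quartile = q,
             stringsAsFactors = FALSE)
}

#' Joint 9p21 x type-I-interferon-cluster stratification
#'
#' The type I interferon gene cluster on 9p21.3 is often co-deleted with
#' CDKN2A/MTAP. Each sample's 9p21 group is crossed with its IFN-cluster
#' state (any HD call among the listed genes vs none) into a joint stratum
#' label such as `"LOSS+IFN-del"`.
#'
#' @param calls a [copy_call_table()].
#' @param ifn_genes character vector of IFN-cluster gene ids.
#' @param ninep21 data.frame (sample_id, group) from [genotype_9p21()].
#' @return data.frame (sample_id, group, ifn_state, stratum); samples with
#'   no observed IFN-cluster call are dropped with a warning.
#' @export
ifn_codeletion_status <- function(calls, ifn_genes, ninep21) {
  if (length(ifn_genes) == 0L) {
    abort_icb("empty IFN gene list", "icb_validation_error")
  }
  sub <- calls[calls$gene_id %in% ifn_genes, , drop = FALSE]
  covered <- unique(sub$sample_id)
  keep <- ninep21$sample_id %in% covered
  if (any(!keep)) {
    warn_icb(sprintf("%d sample(s) without IFN-cluster calls; excluded",
                     sum(!keep)))
  }
  out <- ninep21[keep, c("sample_id", "group"), drop = FALSE]
  any_hd <- tapply(sub$call, sub$sample_id, function(v) any(v == -2L))
  out$ifn_state <- ifelse(any_hd[out$sample_id], "IFN-del", "IFN-intact")
  out$stratum <- paste(out$group, out$ifn_state, sep = "+")
  rownames(out) <- NULL
  out
}
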