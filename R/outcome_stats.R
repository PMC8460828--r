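# Contingency construction, exact and likelihood-ratio tests for response
# proportions, the composite response score, and logistic factor modelling.

#' Derive durable clinical benefit (DCB)
#'
#' DCB is complete/partial response, or stable disease lasting more than 6
#' months. SD with missing PFS time and non-evaluable (NE) responses give
#' NA.
#'
#' @param response RECIST best response (CR/PR/SD/PD/NE), vectorized.
#' @param pfs_time progression-free survival in months.
#' @return logical vector.
#' @export
derive_dcb <- function(response, pfs_time = NA_real_) {
  bad <- !is.na(response) & !(response %in% .response_vocab)
  if (any(bad)) {
    abort_icb(sprintf("response outside vocabulary: '%s'", response[bad][1L]),
              "icb_validation_error")
  }
  pfs_time <- rep_len(pfs_time, length(response))
  out <- rep(NA, length(response))
  out[response %in% c("CR", "PR")] <- TRUE
  out[response == "PD"] <- FALSE
  sd <- !is.na(response) & response == "SD"
  out[sd] <- pfs_time[sd] > 6
  out
}

#' Cross-tabulate two per-sample label vectors
#'
#' @param labels_a,labels_b named vectors (names = sample ids). Samples
#'   outside the intersection or with NA in either label are dropped; the
#'   drop count is reported as attribute `n_dropped`.
#' @return integer matrix (classed `"contingency_table"`).
#' @export
build_contingency <- function(labels_a, labels_b) {
  common <- intersect(names(labels_a), names(labels_b))
  if (!length(common)) {
    abort_icb("no overlapping sample ids between the two label vectors",
              "icb_validation_error")
  }
  a <- labels_a[common]; b <- labels_b[common]
  keep <- !is.na(a) & !is.na(b)
  tab <- table(factor(a[keep]), factor(b[keep]))
  out <- unclass(as.matrix(tab))
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- c("contingency_table", class(out))
  out
}

.as_test_result <- function(method, statistic, p) {
  structure(list(method = method, statistic = statistic, p = p),
            class = "icb_test")
}

#' @export
print.icb_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, p = %g\n", x$method,
              ifelse(is.na(x$statistic), "NA", format(x$statistic)), x$p))
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p is the sum of hypergeometric probabilities of all tables
#' with the observed margins whose point probability does not exceed the
#' observed one (with a 1e-7 relative tolerance). A zero margin yields
#' p = 1 with a warning.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return an object of class `"icb_test"` (method, statistic = odds ratio
#'   estimate, p).
#' @export
fisher_exact_2x2 <- function(table, alternative = "two.sided") {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) {
    abort_icb("fisher_exact_2x2 requires a 2x2 table", "icb_validation_error")
  }
  if (any(table < 0) || any(table != round(table))) {
    abort_icb("counts must be non-negative integers", "icb_validation_error")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warn_icb("zero margin: Fisher p fixed at 1")
    return(.as_test_result("fisher_2x2", NA_real_, 1))
  }
  ft <- stats::fisher.test(table, alternative = alternative)
  .as_test_result("fisher_2x2", unname(ft$estimate), ft$p.value)
}

# Upper bound on the number of margin-preserving tables (product of
# compositions along whichever orientation is smaller); used to decide when
# exhaustive enumeration is refused in favour of the Monte-Carlo mode.
.rxc_table_bound <- function(table) {
  r <- nrow(table); c <- ncol(table)
  min(prod(choose(colSums(table) + r - 1, r - 1)),
      prod(choose(rowSums(table) + c - 1, c - 1)))
}

#' Exact test for an r x c table (Freeman-Halton)
#'
#' Generalises the two-sided Fisher rule: the p-value sums the
#' probabilities of all tables sharing the observed margins whose
#' probability does not exceed the observed table's. For 2x2 input it
#' equals [fisher_exact_2x2()]. When the enumeration bound exceeds
#' `max_tables`, a seeded Monte-Carlo estimate is used if `monte_carlo =
#' TRUE`, otherwise an error is raised.
#'
#' @param table r x c matrix of counts with positive margins.
#' @param max_tables refuse exhaustive enumeration beyond this bound.
#' @param monte_carlo use Monte-Carlo p estimation when too large.
#' @param B Monte-Carlo replicates.
#' @param seed integer seed for the Monte-Carlo mode.
#' @return an `"icb_test"` (method `"fisher_rxc"`).
#' @export
fisher_exact_rxc <- function(table, max_tables = 1e7, monte_carlo = FALSE,
                             B = 1e5, seed = 1L) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort_icb("fisher_exact_rxc requires positive margins", "icb_validation_error")
  }
  if (all(dim(table) == c(2L, 2L))) {
    res <- fisher_exact_2x2(table)
    return(.as_test_result("fisher_rxc", NA_real_, res$p))
  }
  if (.rxc_table_bound(table) > max_tables) {
    if (!monte_carlo) {
      abort_icb(paste("table too large for exhaustive enumeration;",
                      "re-run with monte_carlo = TRUE"),
                "icb_enumeration_error")
    }
    set.seed(seed)
    ft <- stats::fisher.test(table, simulate.p.value = TRUE, B = B)
    return(.as_test_result("fisher_rxc_mc", NA_real_, ft$p.value))
  }
  ft <- stats::fisher.test(table, workspace = 2e7)
  .as_test_result("fisher_rxc", NA_real_, ft$p.value)
}

#' Likelihood-ratio chi-squared (G) test for an r x c table
#'
#' G^2 = 2 * sum O * ln(O/E) with the 0 * ln 0 = 0 convention; p from the
#' chi-squared distribution with (r-1)(c-1) degrees of freedom.
#'
#' @param table r x c matrix of counts with positive margins.
#' @return an `"icb_test"` (statistic = G^2).
#' @export
lr_chisq_test <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort_icb("lr_chisq_test requires positive margins", "icb_validation_error")
  }
  E <- outer(rowSums(table), colSums(table)) / sum(table)
  terms <- ifelse(table > 0, table * log(table / E), 0)
  g2 <- 2 * sum(terms)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  .as_test_result("lr_chisq", g2, stats::pchisq(g2, df, lower.tail = FALSE))
}

#' Compare response rates between two strata
#'
#' @param outcomes named logical vector of responder flags.
#' @param strata named character vector of stratum labels.
#' @param contrast length-2 vector of stratum labels to compare.
#' @return list with per-stratum counts and rates, `rate_ratio`
#'   (larger/smaller), and the 2x2 Fisher test; NA outcomes are dropped and
#'   counted in `n_dropped`.
#' @export
response_rates_compare <- function(outcomes, strata, contrast) {
  stopifnot(length(contrast) == 2L)
  common <- intersect(names(outcomes), names(strata))
  o <- outcomes[common]; s <- strata[common]
  keep <- !is.na(o) & !is.na(s) & s %in% contrast
  n_dropped <- sum(s %in% contrast & is.na(o))
  o <- o[keep]; s <- s[keep]
  n <- c(sum(s == contrast[1L]), sum(s == contrast[2L]))
  if (any(n == 0L)) {
    abort_icb(sprintf("empty stratum: %s", contrast[which(n == 0L)[1L]]),
              "icb_validation_error")
  }
  resp <- c(sum(o[s == contrast[1L]]), sum(o[s == contrast[2L]]))
  rates <- resp / n
  tab <- matrix(c(resp, n - resp), 2L,
                dimnames = list(contrast, c("responder", "non_responder")))
  list(
    stratum = contrast, responders = resp, total = n, rate = rates,
    rate_ratio = max(rates) / max(min(rates), .Machine$double.eps),
    test = fisher_exact_2x2(tab),
    n_dropped = n_dropped
  )
}

#' Composite 9p21 / PD-L1 / TMB response score
#'
#' A sample scores 2 points for TMB strictly above the cohort median, 1
#' point for the hi_hi expression surrogate (both CDKN2A and MTAP above
#' their medians), and 1 point for high immune-cell PD-L1 (IC2+, >= 5%
#' staining). Tiers: low (0), intermediate (1-2), high (3-4). Samples with
#' any missing component are excluded (NA points) with a reason.
#'
#' @param tmb numeric TMB values.
#' @param tmb_median cohort median used for the split (ties at the median
#'   count as low).
#' @param surrogate character labels ("hi_hi"/"lo_lo"/"mixed").
#' @param pdl1_ic PD-L1 immune-cell category ("IC0"/"IC1"/"IC2+").
#' @param sample_id optional ids.
#' @return data.frame (sample_id, tmb_high, surrogate_hi_hi, pdl1_ic_high,
#'   points, tier, excluded_reason).
#' @export
compute_response_score <- function(tmb, tmb_median, surrogate, pdl1_ic,
                                   sample_id = NULL) {
  n <- max(length(tmb), length(surrogate), length(pdl1_ic))
  tmb <- rep_len(tmb, n); surrogate <- rep_len(surrogate, n)
  pdl1_ic <- rep_len(pdl1_ic, n)
  if (is.null(sample_id)) sample_id <- as.character(seq_len(n))
  tmb_high <- tmb > tmb_median
  hi_hi <- surrogate == "hi_hi"
  ic_high <- pdl1_ic == "IC2+"
  reason <- rep(NA_character_, n)
  reason[is.na(tmb)] <- "missing TMB"
  reason[is.na(surrogate)] <- "missing surrogate label"
  reason[is.na(pdl1_ic)] <- "missing PD-L1 IC"
  ok <- is.na(reason)
  points <- rep(NA_integer_, n)
  points[ok] <- 2L * tmb_high[ok] + hi_hi[ok] + ic_high[ok]
  tier <- rep(NA_character_, n)
  tier[ok] <- c("low", "intermediate", "intermediate", "high", "high")[points[ok] + 1L]
  data.frame(sample_id = sample_id, tmb_high = tmb_high,
             surrogate_hi_hi = hi_hi, pdl1_ic_high = ic_high,
             points = points, tier = tier, excluded_reason = reason,
             stringsAsFactors = FALSE)
}

# Penalized (ridge) logistic log-likelihood fit, used as the fallback when
# maximum likelihood separates.
.ridge_logistic <- function(y, X, lambda) {
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    -sum(y * eta - log1p(exp(eta))) + lambda * sum(beta[-1L]^2) / 2
  }
  opt <- stats::optim(rep(0, ncol(X)), nll, method = "BFGS", hessian = TRUE)
  se <- sqrt(diag(solve(opt$hessian)))
  list(coef = opt$par, se = se)
}

#' Logistic regression of responder status on binary/real factors
#'
#' Maximum-likelihood fit with per-factor Wald p-values. Perfect or
#' quasi-perfect separation is flagged; when flagged and `penalty > 0` a
#' ridge-penalized fit is returned instead.
#'
#' @param outcome logical (or 0/1) responder flags.
#' @param covariates data.frame of numeric/logical factors.
#' @param penalty ridge penalty used only as the separation fallback.
#' @return data.frame (term, estimate, se, p) with attributes `converged`
#'   and `separation`.
#' @export
fit_logistic <- function(outcome, covariates, penalty = 0) {
  outcome <- as.logical(outcome)
  keep <- !is.na(outcome) & stats::complete.cases(covariates)
  y <- outcome[keep]
  X <- as.data.frame(lapply(covariates[keep, , drop = FALSE], as.numeric))
  if (length(y) < 10L) {
    abort_icb("logistic fit needs >= 10 complete samples", "icb_validation_error")
  }
  if (length(unique(y)) < 2L) {
    abort_icb("outcome has a single class", "icb_validation_error")
  }
  fit <- suppressWarnings(stats::glm(y ~ ., data = X, family = stats::binomial()))
  co <- summary(fit)$coefficients
  separated <- any(abs(co[, "Estimate"]) > 15) ||
    any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
  if (separated && penalty > 0) {
    Xm <- cbind(1, as.matrix(X))
    rf <- .ridge_logistic(as.numeric(y), Xm, penalty)
    out <- data.frame(term = c("(Intercept)", names(X)), estimate = rf$coef,
                      se = rf$se,
                      p = 2 * stats::pnorm(-abs(rf$coef / rf$se)),
                      stringsAsFactors = FALSE)
    attr(out, "converged") <- TRUE
    attr(out, "separation") <- TRUE
    attr(out, "penalized") <- TRUE
    return(out)
  }
  out <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                    se = co[, "Std. Error"], p = co[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "converged") <- fit$converged
  attr(out, "separation") <- separated
  attr(out, "penalized") <- FALSE
  if (separated) warn_icb("possible separation in logistic fit; consider penalty > 0")
  out
}

#' Integer score weights from logistic coefficients
#'
#' Each factor's points are its coefficient magnitude divided by the
#' smallest magnitude, rounded, floored at 1. This is how a 2:1:1
#' TMB/9p21/PD-L1 weighting arises when the TMB coefficient is about twice
#' the others.
#'
#' @param coefs named numeric coefficients (intercept excluded).
#' @return named integer vector of points.
#' @export
derive_score_weights <- function(coefs) {
  if (length(coefs) < 2L) {
    abort_icb("need >= 2 factor coefficients", "icb_validation_error")
  }
  m <- min(abs(coefs))
  if (m == 0) {
    abort_icb("zero minimum coefficient; weights undefined", "icb_validation_error")
  }
  w <- pmax(1L, as.integer(round(abs(coefs) / m)))
  names(w) <- names(coefs)
  w
}
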