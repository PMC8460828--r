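test_that("durable clinical benefit follows the CR/PR-or-durable-SD rule", {
  expect_true(derive_dcb("PR", 1))
  expect_true(derive_dcb("CR", NA))
  expect_true(derive_dcb("SD", 7))
  expect_false(derive_dcb("SD", 5))
  expect_false(derive_dcb("PD", 20))
  expect_true(is.na(derive_dcb("SD", NA)))
  expect_error(derive_dcb("RESPONDER"), class = "icb_validation_error")
})

test_that("contingency construction matches a loop-based counting oracle", {
  # the 9-sample resectable-melanoma configuration
  lab <- stats::setNames(rep(c("hi_hi", "lo_lo"), c(4, 5)), paste0("s", 1:9))
  resp <- stats::setNames(c("R", "R", "R", "N", rep("N", 5)), paste0("s", 1:9))
  tab <- build_contingency(lab, resp)
  expect_equal(unclass(tab)[c("hi_hi", "lo_lo"), c("R", "N")],
               matrix(c(3, 0, 1, 5), 2,
                      dimnames = list(c("hi_hi", "lo_lo"), c("R", "N"))),
               ignore_attr = TRUE)

  expect_error(build_contingency(stats::setNames("A", "x"),
                                 stats::setNames("B", "y")),
               class = "icb_validation_error")

  set.seed(5)
  a <- stats::setNames(sample(letters[1:3], 50, TRUE), sprintf("s%02d", 1:50))
  b <- stats::setNames(sample(LETTERS[1:2], 50, TRUE), sprintf("s%02d", 1:50))
  tab2 <- build_contingency(a, b)
  for (r in rownames(tab2)) for (c in colnames(tab2)) {
    expect_equal(tab2[r, c], sum(a == r & b == c))
  }
})

test_that("Fisher 2x2 equals hypergeometric enumeration and is symmetric", {
  set.seed(12)
  for (i in 1:60) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    p <- fisher_exact_2x2(tab)$p
    expect_equal(p, oracle_fisher_2x2(tab), tolerance = 1e-10)
    expect_equal(fisher_exact_2x2(t(tab))$p, p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[2:1, 2:1])$p, p, tolerance = 1e-12)
  }
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p, 1)
  expect_warning(z <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
  expect_equal(z$p, 1)
})

test_that("exact-test type-I error is conservative under the null", {
  set.seed(31)
  n_sim <- 4000
  rej <- 0
  for (i in 1:n_sim) {
    x <- rbinom(1, 12, 0.4); y <- rbinom(1, 14, 0.4)
    tab <- matrix(c(x, 12 - x, y, 14 - y), 2, byrow = TRUE)
    if (any(colSums(tab) == 0)) next
    if (fisher_exact_2x2(tab)$p < 0.05) rej <- rej + 1
  }
  expect_lte(rej / n_sim, 0.05)
})

test_that("r x c exact test agrees with 2x2 and with brute-force enumeration", {
  tab <- matrix(c(7, 3, 2, 9), 2)
  expect_equal(fisher_exact_rxc(tab)$p, fisher_exact_2x2(tab)$p,
               tolerance = 1e-12)

  # brute-force Freeman-Halton over all margin-preserving 3x2 tables
  obs <- matrix(c(2, 0, 0, 2, 1, 1), 3, byrow = TRUE)
  rs <- rowSums(obs); cs <- colSums(obs)
  prob_table <- function(m) {
    exp(sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(sum(m) + 1) -
          sum(lgamma(m + 1)))
  }
  p_obs <- prob_table(obs)
  p_sum <- 0
  for (a in 0:rs[1]) for (b in 0:rs[2]) {
    m <- cbind(c(a, b, cs[1] - a - b), c(rs[1] - a, rs[2] - b,
                                         cs[2] - rs[1] - rs[2] + a + b))
    if (any(m < 0)) next
    pm <- prob_table(m)
    if (pm <= p_obs * (1 + 1e-7)) p_sum <- p_sum + pm
  }
  expect_equal(fisher_exact_rxc(obs)$p, p_sum, tolerance = 1e-9)

  big <- matrix(500L, 6, 6)
  expect_error(fisher_exact_rxc(big, max_tables = 10),
               class = "icb_enumeration_error")
  mc <- fisher_exact_rxc(obs, max_tables = 10, monte_carlo = TRUE,
                         B = 2000, seed = 7)
  expect_equal(mc$p, p_sum, tolerance = 0.05)
})

test_that("likelihood-ratio G2 matches direct summation and its null", {
  set.seed(8)
  for (i in 1:30) {
    tab <- matrix(rpois(6, 15) + 1, 2)
    res <- lr_chisq_test(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    g2 <- 2 * sum(tab * log(tab / E))
    expect_equal(res$statistic, g2, tolerance = 1e-9)
    expect_equal(res$p, pchisq(g2, 2, lower.tail = FALSE), tolerance = 1e-12)
  }
  even <- matrix(c(10, 20, 5, 10), 2)  # equal row proportions
  res <- lr_chisq_test(even)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
})

test_that("response-rate comparison reports rates, ratio and Fisher p", {
  out <- stats::setNames(c(rep(TRUE, 27), rep(FALSE, 18),
                           rep(TRUE, 9), rep(FALSE, 32)),
                         sprintf("s%03d", 1:86))
  strat <- stats::setNames(rep(c("hi_hi", "lo_lo"), c(45, 41)), names(out))
  rc <- response_rates_compare(out, strat, c("hi_hi", "lo_lo"))
  expect_equal(rc$rate, c(0.6, 9 / 41))
  expect_equal(rc$rate_ratio, 0.6 / (9 / 41), tolerance = 1e-12)
  expect_equal(rc$test$p, 0.0004, tolerance = 0.15)

  same <- suppressWarnings(response_rates_compare(out[1:20], stats::setNames(
    rep(c("x", "y"), 10), names(out)[1:20]), c("x", "y")))
  expect_equal(same$rate[1], same$rate[2])
  expect_equal(same$test$p, 1)
})

test_that("the response score is the deterministic 2/1/1 additive rule", {
  sc <- compute_response_score(
    tmb = c(20, 1, 20, 5, NA),
    tmb_median = 5,
    surrogate = c("hi_hi", "lo_lo", "mixed", "hi_hi", "hi_hi"),
    pdl1_ic = c("IC2+", "IC0", "IC1", "IC2+", "IC1")
  )
  expect_equal(sc$points, c(4L, 0L, 2L, 2L, NA))
  expect_identical(sc$tier, c("high", "low", "intermediate", "intermediate", NA))
  expect_identical(sc$excluded_reason[5], "missing TMB")
  # tie at the median counts as TMB-low
  expect_equal(sc$points[4], 2L)
  # tier boundaries partition 0..4
  all_pts <- compute_response_score(
    tmb = c(1, 1, 10, 10, 10), tmb_median = 5,
    surrogate = c("lo_lo", "hi_hi", "lo_lo", "hi_hi", "hi_hi"),
    pdl1_ic = c("IC0", "IC0", "IC1", "IC0", "IC2+")
  )
  expect_equal(all_pts$points, 0:4)
  expect_identical(all_pts$tier,
                   c("low", "intermediate", "intermediate", "high", "high"))
})

test_that("logistic factor model recovers simulated coefficients", {
  set.seed(101)
  n <- 2000
  x <- data.frame(tmb = rbinom(n, 1, 0.5), surr = rbinom(n, 1, 0.5),
                  pdl1 = rbinom(n, 1, 0.3))
  eta <- -1 + 0.7 * x$tmb + 0.35 * x$surr + 0.35 * x$pdl1
  y <- runif(n) < plogis(eta)
  fit <- fit_logistic(y, x)
  est <- fit$estimate[match(c("tmb", "surr", "pdl1"), fit$term)]
  expect_equal(est, c(0.7, 0.35, 0.35), tolerance = 0.15)

  # null covariate stays null
  set.seed(103)
  x0 <- data.frame(z = rnorm(500))
  y0 <- runif(500) < 0.4
  f0 <- fit_logistic(y0, x0)
  expect_lt(abs(f0$estimate[f0$term == "z"]), 0.25)
  expect_gt(f0$p[f0$term == "z"], 0.05)

  expect_error(fit_logistic(rep(TRUE, 20), data.frame(a = rnorm(20))),
               class = "icb_validation_error")
})

test_that("separation is flagged and the penalized fallback returns finite fits", {
  y <- c(rep(FALSE, 10), rep(TRUE, 10))
  x <- data.frame(d = as.numeric(y))  # perfect separation
  fit <- suppressWarnings(fit_logistic(y, x))
  expect_true(attr(fit, "separation"))
  pen <- fit_logistic(y, x, penalty = 1)
  expect_true(attr(pen, "penalized"))
  expect_true(all(is.finite(pen$estimate)))
})

test_that("score weights follow round-to-smallest with floor one", {
  expect_equal(unname(derive_score_weights(c(0.70, 0.35, 0.36))), c(2L, 1L, 1L))
  expect_equal(unname(derive_score_weights(c(0.5, 0.5))), c(1L, 1L))
  expect_equal(unname(derive_score_weights(c(0.9, 0.3, 0.3))), c(3L, 1L, 1L))
  expect_error(derive_score_weights(c(0, 0.5)), class = "icb_validation_error")
})
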