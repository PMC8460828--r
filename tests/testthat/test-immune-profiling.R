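test_that("marker scores are set means of log2 expression", {
  m <- matrix(c(2, 4, 6,
                4, 8, 2,
                1, 1, 1), 3, 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), paste0("s", 1:3)))
  gs <- gene_set_collection(list(two = c("A", "B"), one = "C",
                                 absent = "ZZZ"))
  expect_warning(marker_abundance_scores(expression_matrix(m), gs), "absent")
  sc <- suppressWarnings(marker_abundance_scores(expression_matrix(m), gs))
  expect_equal(unname(sc["two", ]), c(3, 6, 4))
  expect_equal(unname(sc["one", ]), c(1, 1, 1))

  # oracle: loop-based mean over random sets
  x <- make_expr(50, 8, seed = 5)
  sets <- lapply(1:5, function(i) sample(rownames(x), sample(3:10, 1)))
  names(sets) <- paste0("set", 1:5)
  sc2 <- marker_abundance_scores(x, gene_set_collection(sets))
  for (nm in names(sets)) {
    for (s in colnames(x)) {
      expect_equal(sc2[nm, s], mean(x[sets[[nm]], s]), tolerance = 1e-12)
    }
  }
})

test_that("marker scores are monotone in any member gene's expression", {
  x <- make_expr(20, 6, seed = 8)
  gs <- gene_set_collection(list(f = rownames(x)[1:4]))
  base <- marker_abundance_scores(x, gs)
  bumped <- unclass(x)
  bumped[2, 3] <- bumped[2, 3] + 5
  up <- marker_abundance_scores(expression_matrix(bumped), gs)
  expect_gt(up["f", 3], base["f", 3])
  expect_equal(up["f", -3], base["f", -3])
})

test_that("ssGSEA matches the brute-force running-sum oracle on small cases", {
  set.seed(21)
  for (rep in 1:20) {
    n_genes <- sample(5:12, 1)
    vals <- round(runif(n_genes, 0, 10), 2)
    if (rep %% 3 == 0) vals[2] <- vals[1]  # inject ties
    genes <- sprintf("G%02d", seq_len(n_genes))
    names(vals) <- genes
    m <- cbind(s1 = vals, s2 = rev(vals))
    rownames(m) <- genes
    set_genes <- sample(genes, sample(2:(n_genes - 1), 1))
    sc <- ssgsea_scores(expression_matrix(m),
                        gene_set_collection(list(p = set_genes)),
                        alpha = 0.25, normalize = FALSE)
    expect_equal(sc["p", "s1"],
                 oracle_ssgsea_sample(m[, "s1"], set_genes, 0.25),
                 tolerance = 1e-12)
    expect_equal(sc["p", "s2"],
                 oracle_ssgsea_sample(m[, "s2"], set_genes, 0.25),
                 tolerance = 1e-12)
  }
})

test_that("ssGSEA is rank-based: identical orderings and monotone transforms", {
  x <- make_expr(30, 4, seed = 31)
  gs <- gene_set_collection(list(p1 = rownames(x)[1:5], p2 = rownames(x)[10:20]))
  sc <- ssgsea_scores(x, gs, normalize = FALSE)

  # duplicate sample with a shifted copy: same ranks, same score
  shifted <- unclass(x)
  shifted[, 2] <- shifted[, 1] + 7
  sc2 <- ssgsea_scores(expression_matrix(shifted), gs, normalize = FALSE)
  expect_equal(sc2[, 2], sc2[, 1])

  # strictly monotone per-sample transform leaves scores unchanged
  mono <- expression_matrix(unclass(x)^3 / 100)
  expect_equal(ssgsea_scores(mono, gs, normalize = FALSE), sc,
               ignore_attr = TRUE)

  expect_error(
    ssgsea_scores(x, gene_set_collection(list(all = rownames(x)))),
    class = "icb_validation_error"
  )
})

test_that("TCR diversity reproduces closed-form entropies", {
  cl <- cbind(s1 = c(10, 0, 0, 0), s2 = c(1, 1, 1, 1), s3 = c(2, 1, 1, 0))
  rownames(cl) <- paste0("c", 1:4)
  d <- tcr_diversity(cl)
  expect_equal(d$richness, c(1, 4, 3))
  expect_equal(d$shannon, c(0, log(4), -sum(c(.5, .25, .25) * log(c(.5, .25, .25)))),
               tolerance = 1e-12)
  expect_equal(d$shannon[3], 1.0397, tolerance = 1e-4)

  bits <- tcr_diversity(cl, bits = TRUE)
  expect_equal(bits$shannon[2], 2)

  z <- cbind(s1 = c(0, 0), s2 = c(1, 1))
  rownames(z) <- c("c1", "c2")
  expect_warning(dz <- tcr_diversity(z), "all-zero")
  expect_true(is.na(dz$shannon[1]))
})

test_that("entropy is bounded by log richness with equality at uniform", {
  set.seed(77)
  for (i in 1:100) {
    k <- sample(1:30, 1)
    counts <- matrix(rpois(k, 20) + 1, k, 1,
                     dimnames = list(paste0("c", 1:k), "s"))
    d <- tcr_diversity(counts)
    expect_gte(d$shannon, 0)
    expect_lte(d$shannon, log(d$richness) + 1e-12)
  }
})

test_that("differential abundance exact p matches rank-assignment enumeration", {
  set.seed(13)
  a <- round(rnorm(4, 0, 1), 3)
  b <- round(rnorm(5, 1, 1), 3)
  sc <- matrix(c(a, b), 1, 9,
               dimnames = list("f", paste0("s", 1:9)))
  groups <- make_groups(colnames(sc), 4)
  res <- differential_abundance(sc, groups, c("A", "B"), exact = TRUE)
  expect_equal(res$p, oracle_wilcoxon_exact(a, b), tolerance = 1e-12)
  expect_equal(res$log2_fc, mean(a) - mean(b), tolerance = 1e-12)
})

test_that("differential abundance flags a seeded shift and is null on equal groups", {
  set.seed(42)
  shift <- matrix(c(rnorm(10, 2, 0.5), rnorm(10, 0, 0.5)), 1, 20,
                  dimnames = list("shifted", paste0("s", 1:20)))
  flat <- matrix(rep(1:10, 2), 1, 20,
                 dimnames = list("flat", colnames(shift)))
  sc <- rbind(shift, flat)
  groups <- make_groups(colnames(sc), 10)
  res <- differential_abundance(sc, groups, c("A", "B"))
  expect_lt(res$q[res$feature == "shifted"], 0.05)
  expect_gte(res$p[res$feature == "flat"], 0.99)
  expect_equal(res$log2_fc[res$feature == "flat"], 0)
  expect_true(all(res$q >= res$p))
})

test_that("under permuted labels the p < 0.05 rate stays nominal", {
  set.seed(202)
  sc <- matrix(rnorm(30 * 40), 30, 40,
               dimnames = list(paste0("f", 1:30), paste0("s", 1:40)))
  hits <- 0; total <- 0
  for (perm in 1:40) {
    groups <- stats::setNames(sample(rep(c("A", "B"), 20)), colnames(sc))
    res <- differential_abundance(sc, groups, c("A", "B"))
    hits <- hits + sum(res$p < 0.05)
    total <- total + nrow(res)
  }
  # binomial tolerance around the nominal level
  expect_lt(abs(hits / total - 0.05), 3 * sqrt(0.05 * 0.95 / total) + 0.01)
})
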