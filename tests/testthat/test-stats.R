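test_that("permutation correlation reports the exact Pearson r", {
  set.seed(1)
  for (i in 1:10) {
    x <- rnorm(15); y <- rnorm(15)
    expect_equal(perm_corr_test(x, y, n_perm = 10, seed = i)$r, cor(x, y),
                 tolerance = 1e-12)
  }
})

test_that("a perfect linear relation attains the minimum p", {
  x <- 1:10
  res <- perm_corr_test(x, 2 * x, n_perm = 499, seed = 3)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 500)
})

test_that("permutation p stays in its attainable range and is seeded", {
  set.seed(2)
  x <- rnorm(12); y <- rnorm(12)
  a <- perm_corr_test(x, y, n_perm = 299, seed = 7)
  b <- perm_corr_test(x, y, n_perm = 299, seed = 7)
  expect_identical(a, b)
  expect_gte(a$p, 1 / 300)
  expect_lte(a$p, 1)
  expect_error(perm_corr_test(rep(1, 10), rnorm(10)), "constant")
  expect_error(perm_corr_test(rnorm(4), rnorm(5)), "same length")
})

test_that("sampled permutation p approaches the exhaustive p at n = 6", {
  set.seed(4)
  for (i in 1:3) {
    x <- rnorm(6); y <- rnorm(6)
    exact <- exact_perm_p(x, y)
    sampled <- perm_corr_test(x, y, n_perm = 4000, seed = i)$p
    expect_lt(abs(sampled - exact),
              3 * sqrt(exact * (1 - exact) / 4000) + 2 / 4000 + 0.01)
    # the exhaustive p is invariant under jointly permuting the pairs
    o <- sample(6)
    expect_equal(exact_perm_p(x[o], y[o]), exact)
  }
})

test_that("bootstrap interval collapses for an exact relation and is seeded", {
  x <- c(1.2, 2.5, 3.1, 4.8, 5.0, 6.3, 7.7)
  ci <- bootstrap_ci(x, x, n_boot = 200, seed = 5)
  expect_equal(c(ci$lo, ci$hi), c(1, 1))
  set.seed(6)
  y <- x + rnorm(7)
  a <- bootstrap_ci(x, y, n_boot = 200, seed = 9)
  b <- bootstrap_ci(x, y, n_boot = 200, seed = 9)
  expect_identical(a, b)
  expect_lte(a$lo, a$hi)
})

test_that("bootstrap interval covers a known correlation about 95% of the time", {
  set.seed(19)
  rho <- 0.5
  hits <- vapply(1:120, function(i) {
    z <- rnorm(200); e <- rnorm(200)
    x <- z
    y <- rho * z + sqrt(1 - rho^2) * e
    ci <- bootstrap_ci(x, y, n_boot = 300, seed = i)
    ci$lo <= rho && rho <= ci$hi
  }, logical(1))
  expect_gte(mean(hits), 0.87)
  expect_lte(mean(hits), 0.99)
})

test_that("partial correlation matches the lm-residual construction", {
  set.seed(8)
  for (i in 1:10) {
    n <- 40
    z <- rnorm(n)
    x <- 0.5 * z + rnorm(n)
    y <- -0.3 * z + rnorm(n)
    pc <- partial_corr(x, y, z)
    oracle <- cor(residuals(lm(x ~ z)), residuals(lm(y ~ z)))
    expect_equal(pc$r, oracle, tolerance = 1e-10)
  }
})

test_that("partial correlation is near the raw one for an irrelevant control", {
  set.seed(9)
  n <- 500
  x <- rnorm(n); y <- 0.4 * x + rnorm(n); z <- rnorm(n)
  pc <- partial_corr(x, y, z)
  expect_lt(abs(pc$r - cor(x, y)), 0.05)
  expect_error(partial_corr(1:8, rnorm(8), 2 * (1:8)), "degenerate")
})

test_that("partial correlation permutation variant agrees with the t tier", {
  set.seed(10)
  n <- 60
  z <- rnorm(n); x <- 0.6 * z + rnorm(n); y <- 0.6 * z + 0.5 * x + rnorm(n)
  pt_ <- partial_corr(x, y, z, method = "t")
  pp <- partial_corr(x, y, z, method = "permutation", n_perm = 999, seed = 2)
  expect_equal(pt_$r, pp$r)
  expect_equal(pt_$p < 0.01, pp$p < 0.01)
})

test_that("Mann-Whitney U equals the pair-counting oracle, ties included", {
  expect_equal(mann_whitney(c(5, 6, 7), c(1, 2))$U, 6)  # maximal nx * ny
  same <- mann_whitney(c(1, 2, 3), c(3, 2, 1))
  expect_equal(same$p, 1)
  set.seed(11)
  for (i in 1:25) {
    x <- sample(1:6, 4, replace = TRUE)
    y <- sample(1:6, 4, replace = TRUE)
    expect_equal(mann_whitney(x, y)$U, brute_U(x, y))
  }
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney agrees with the standard implementation", {
  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(9); y <- rnorm(7, mean = 0.8)
    mw <- mann_whitney(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(mw$U, unname(ref$statistic))
    expect_equal(mw$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Cohen's kappa matches hand computations and is symmetric", {
  expect_equal(cohens_kappa(c("a", "b", "a"), c("a", "b", "a")), 1)
  expect_equal(cohens_kappa(c("+", "+", "-", "-"), c("+", "-", "+", "-")), 0)
  set.seed(13)
  a <- sample(c("+", "-", "0"), 40, replace = TRUE)
  b <- sample(c("+", "-", "0"), 40, replace = TRUE)
  expect_equal(cohens_kappa(a, b), cohens_kappa(b, a))
  # independent labels: mean kappa near zero over replicates
  ks <- vapply(1:200, function(i) {
    cohens_kappa(sample(c("x", "y"), 30, replace = TRUE),
                 sample(c("x", "y"), 30, replace = TRUE))
  }, numeric(1))
  expect_lt(abs(mean(ks)), 0.05)
  # both constant and identical: perfect agreement by definition
  expect_equal(cohens_kappa(c("a", "a"), c("a", "a")), 1)
})

test_that("average pairwise kappa is the mean over annotator pairs", {
  r1 <- c("a", "b", "a", "b")
  r2 <- r1                          # kappa 1 with r1
  r3 <- c("a", "a", "b", "b")       # kappa 0 with both
  expect_equal(average_pairwise_kappa(list(r1, r2, r3)), 1 / 3)
  expect_error(average_pairwise_kappa(list(r1)), "two annotators")
})

test_that("normality check flags skewed data and rejects degenerate input", {
  set.seed(14)
  norm_p <- vapply(1:40, function(i) normality_check(rnorm(70))$p, numeric(1))
  exp_p <- vapply(1:40, function(i) normality_check(rexp(70))$p, numeric(1))
  expect_gte(mean(norm_p > 0.05), 0.85)
  expect_gte(mean(exp_p < 0.05), 0.9)
  expect_error(normality_check(rep(2, 10)), "constant")
})

test_that("the correlation screen has full structure and fixed seeds", {
  sim <- simulate_cohort(sim_config(n_users = 25, seed = 15))
  sel <- select_cohort(sim$users, sim$posts)
  feat <- transition_features(sel$cohort, "post_with_silence")
  scales <- sel$cohort$users[sel$cohort$users$user_id %in% feat$user_id,
                             c("user_id", "ope", "con", "ext", "agr",
                               "neu", "swl", "cesd")]
  scr <- correlation_screen(feat, scales, n_perm = 99, n_boot = 50, seed = 3)
  expect_equal(nrow(scr), 7 * 15)
  expect_setequal(unique(scr$scale),
                  c("ope", "con", "ext", "agr", "neu", "swl", "cesd"))
  expect_equal(scr$r2, scr$r^2, tolerance = 1e-12)
  ok <- !is.na(scr$p)
  expect_true(all(scr$tier[ok & scr$p < 0.01] == "significant"))
  expect_true(all(scr$tier[ok & scr$p >= 0.01 & scr$p < 0.05] == "trend"))
  expect_true(all(scr$ci_lo[ok] <= scr$ci_hi[ok]))
  scr2 <- correlation_screen(feat, scales, n_perm = 99, n_boot = 50, seed = 3)
  expect_identical(as.data.frame(scr), as.data.frame(scr2))
  m <- screen_matrix(scr)
  expect_equal(rownames(m)[1], "n_occ")
  expect_equal(dim(m), c(8, 15))
})

test_that("the screen detects a planted effect and errors on misalignment", {
  set.seed(16)
  n <- 100
  scale_v <- rnorm(n)
  features <- data.frame(user_id = sprintf("u%03d", 1:n),
                         f1 = scale_v + rnorm(n, sd = sqrt(1 / 0.33 - 1)),
                         f2 = rnorm(n), stringsAsFactors = FALSE)
  scales <- data.frame(user_id = sprintf("u%03d", 1:n), s1 = scale_v,
                       stringsAsFactors = FALSE)
  scr <- correlation_screen(features, scales, n_perm = 999, n_boot = 100,
                            seed = 4)
  expect_equal(scr$tier[scr$feature == "f1"], "significant")

  bad <- scales; bad$user_id[1] <- "zzz"
  expect_error(correlation_screen(features, bad, seed = 1), "zzz")
})

test_that("a fully null screen reaches the trend tier at about the nominal rate", {
  set.seed(18)
  n <- 70
  ids <- sprintf("u%03d", 1:n)
  features <- data.frame(user_id = ids, matrix(rnorm(n * 15), n, 15),
                         stringsAsFactors = FALSE)
  scales <- data.frame(user_id = ids, matrix(rnorm(n * 7), n, 7),
                       stringsAsFactors = FALSE)
  scr <- correlation_screen(features, scales, n_perm = 199, n_boot = 50,
                            seed = 6)
  share <- mean(scr$p < 0.05)
  expect_gte(share, 0.005)
  expect_lte(share, 0.12)
})

test_that("constant feature columns yield NA rows, not failures", {
  features <- data.frame(user_id = c("a", "b", "c", "d", "e"),
                         f1 = c(0, 0, 0, 0, 0), f2 = c(1, 2, 3, 4, 5),
                         stringsAsFactors = FALSE)
  scales <- data.frame(user_id = c("a", "b", "c", "d", "e"),
                       s1 = c(2, 4, 5, 7, 9), stringsAsFactors = FALSE)
  scr <- correlation_screen(features, scales, n_perm = 99, n_boot = 50,
                            seed = 2)
  expect_true(is.na(scr$r[scr$feature == "f1"]))
  expect_equal(scr$tier[scr$feature == "f1"], "ns")
  expect_false(is.na(scr$r[scr$feature == "f2"]))
})
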