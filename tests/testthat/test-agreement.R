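test_that("Fleiss' kappa matches perfect agreement and the formula oracle", {
  m_perfect <- cbind(c(1, 2, 3, 4, 2), c(1, 2, 3, 4, 2), c(1, 2, 3, 4, 2))
  expect_equal(fleiss_kappa(m_perfect)$estimate, 1)
  # small instances against the independent pairwise-agreement oracle
  set.seed(21)
  for (i in 1:10) {
    m <- matrix(sample(1:4, 8 * 5, TRUE), 8, 5)
    k <- fleiss_kappa(m)
    expect_equal(k$estimate, oracle_fleiss(m), tolerance = 1e-12)
    expect_lte(k$estimate, 1)
  }
  # missing ratings are deleted row-wise before computation
  m <- matrix(sample(1:3, 10 * 4, TRUE), 10, 4)
  m_na <- rbind(m, c(1, NA, 2, 3))
  expect_equal(fleiss_kappa(m_na)$estimate, fleiss_kappa(m)$estimate)
  # single observed category: expected agreement 1, kappa undefined
  expect_true(fleiss_kappa(matrix(1, 5, 3))$degenerate)
})

test_that("Fleiss' kappa is near zero for independent random ratings", {
  set.seed(99)
  m <- matrix(sample(1:4, 1000 * 6, TRUE), 1000, 6)
  k <- fleiss_kappa(m)
  expect_lt(abs(k$estimate), 0.05)
  expect_gt(k$p_value, 1e-4) # no evidence of agreement
})

test_that("Cohen's kappa matches hand computation and the oracle", {
  expect_equal(cohen_kappa(c(1, 2, 3, 1), c(1, 2, 3, 1))$estimate, 1)
  # classic 2x2 hand example: po = 0.7, pe = 0.5 -> kappa = 0.4
  r1 <- c(rep("A", 25), rep("A", 25), rep("B", 5), rep("B", 45))
  r2 <- c(rep("A", 25), rep("B", 25), rep("A", 5), rep("B", 45))
  k <- cohen_kappa(r1, r2)
  expect_equal(k$estimate, (0.7 - 0.5) / 0.5, tolerance = 1e-12)
  set.seed(31)
  for (i in 1:10) {
    a <- sample(letters[1:3], 10, TRUE)
    b <- sample(letters[1:3], 10, TRUE)
    if (length(unique(c(a, b))) < 2 || oracle_cohen(a, b) %in% c(NaN)) next
    expect_equal(cohen_kappa(a, b)$estimate, oracle_cohen(a, b),
                 tolerance = 1e-12)
  }
  # independent random ratings: kappa near zero
  a <- sample(1:3, 2000, TRUE); b <- sample(1:3, 2000, TRUE)
  expect_lt(abs(cohen_kappa(a, b)$estimate), 0.05)
  expect_true(cohen_kappa(rep("A", 5), rep("A", 5))$degenerate)
})

test_that("Spearman rho matches the exact rank formula", {
  x <- 1:5
  y <- c(3, 1, 4, 5, 2)
  r <- spearman_ci(x, y, n_boot = 50, seed = 1)
  # no ties: rho = 1 - 6*sum(d^2)/(n(n^2-1)) = 1 - 96/120
  expect_equal(r$estimate, 0.2, tolerance = 1e-12)
  expect_equal(r$estimate, oracle_spearman(x, y), tolerance = 1e-12)
  # monotone relationships and tie handling against the oracle
  expect_equal(spearman_ci(1:10, exp(1:10), n_boot = 10)$estimate, 1)
  expect_equal(spearman_ci(1:10, -(1:10)^3, n_boot = 10)$estimate, -1)
  set.seed(5)
  for (i in 1:10) {
    a <- sample(1:6, 12, TRUE) # ties likely
    b <- sample(1:6, 12, TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(spearman_ci(a, b, n_boot = 10)$estimate,
                 oracle_spearman(a, b), tolerance = 1e-12)
  }
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  set.seed(8)
  x <- rlnorm(30); y <- x + rnorm(30)
  base <- spearman_ci(x, y, n_boot = 10)$estimate
  expect_equal(spearman_ci(log(x), y, n_boot = 10)$estimate, base)
  expect_equal(spearman_ci(x, y^3, n_boot = 10)$estimate, base)
  expect_equal(spearman_ci(-1 / x, y, n_boot = 10)$estimate, base)
})

test_that("bootstrap CIs are reproducible and tighten with n", {
  set.seed(13)
  x <- rnorm(1000); y <- 0.6 * x + 0.8 * rnorm(1000)
  widths <- vapply(c(10, 100, 1000), function(n) {
    r <- spearman_ci(x[1:n], y[1:n], n_boot = 500, seed = 42)
    r$ci_high - r$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  r1 <- spearman_ci(x, y, n_boot = 200, seed = 7)
  r2 <- spearman_ci(x, y, n_boot = 200, seed = 7)
  expect_identical(r1$ci_low, r2$ci_low)
  expect_true(r1$ci_low <= r1$estimate && r1$estimate <= r1$ci_high)
  expect_true(spearman_ci(rep(1, 10), 1:10, n_boot = 10)$degenerate)
  expect_error(spearman_ci(1:3, 1:3), "at least 4")
})

test_that("rmcorr recovers exact within-subject relationships", {
  x <- rep(1:10, 2)
  sub <- rep(c("s1", "s2"), each = 10)
  # y = x + subject offset, no noise: perfect common slope
  y <- x + ifelse(sub == "s1", 0, 50)
  # suppress the F-test-on-perfect-fit warning; the estimate is the point here
  r <- suppressWarnings(rmcorr(sub, x, y))
  expect_equal(r$estimate, 1)
  expect_equal(suppressWarnings(rmcorr(sub, x, -y))$estimate, -1)
  expect_equal(r$df, 20 - 2 - 1)
})

test_that("rmcorr is invariant to per-subject shifts and drops singletons", {
  set.seed(17)
  sub <- rep(paste0("s", 1:6), each = 8)
  x <- rnorm(48)
  y <- 0.6 * x + rnorm(48, sd = 0.5)
  base <- rmcorr(sub, x, y)
  shifts <- rnorm(6)[as.integer(factor(sub))]
  shifted <- rmcorr(sub, x + shifts, y + 3 * shifts)
  expect_equal(shifted$estimate, base$estimate, tolerance = 1e-10)
  expect_equal(shifted$df, base$df)
  # a subject with a single observation is dropped with a warning
  sub2 <- c(sub, "lonely"); x2 <- c(x, 1); y2 <- c(y, 1)
  expect_warning(r2 <- rmcorr(sub2, x2, y2), "fewer than 2")
  expect_equal(r2$estimate, base$estimate)
  expect_error(suppressWarnings(rmcorr(c("a", "b"), 1:2, 1:2)),
               "at least two subjects")
})

test_that("agreement estimates stay within [-1, 1] on random data", {
  set.seed(23)
  for (i in 1:10) {
    m <- matrix(sample(1:3, 6 * 4, TRUE), 6, 4)
    k <- fleiss_kappa(m)
    if (!k$degenerate) expect_true(abs(k$estimate) <= 1)
    s <- spearman_ci(rnorm(10), rnorm(10), n_boot = 10)
    expect_true(abs(s$estimate) <= 1)
  }
})

test_that("stats tables export all result fields", {
  res <- list(a = spearman_ci(1:10, (1:10)^2, n_boot = 10, seed = 1),
              b = cohen_kappa(c(1, 2, 1), c(1, 2, 2)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stats_table(res, path)
  tab <- read.delim(path)
  expect_equal(tab$name, c("a", "b"))
  expect_equal(tab$estimate[1], 1)
})
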