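test_that("ICC(1,1) matches a from-scratch ANOVA computation", {
  # perfect agreement
  x <- c(1, 2.5, 4, 8)
  expect_equal(iccOnewaySingle(x, x)$icc, 1)
  # worked subjects {(1,2),(3,4),(5,6),(7,8)} against the ANOVA oracle
  o1 <- c(1, 3, 5, 7); o2 <- c(2, 4, 6, 8)
  got <- iccOnewaySingle(o1, o2)
  expect_equal(got$icc, oracleIcc(o1, o2), tolerance = 1e-12)
  # random data, same equivalence to 1e-10
  set.seed(14)
  a <- rnorm(30); b <- a + rnorm(30, sd = 0.5)
  expect_lt(abs(iccOnewaySingle(a, b)$icc - oracleIcc(a, b)), 1e-10)
  # CI brackets the estimate
  expect_lte(got$ci[1], got$icc)
  expect_gte(got$ci[2], got$icc)
  # degenerate constant input flagged, not an error
  z <- iccOnewaySingle(rep(2, 5), rep(2, 5))
  expect_equal(z$icc, 1)
  expect_true(z$degenerate)
  expect_error(iccOnewaySingle(1, 2), "at least 2")
})

test_that("ICC is invariant to a common affine rescaling and near 0 under the null", {
  set.seed(7)
  a <- rnorm(40); b <- 0.8 * a + rnorm(40, sd = 0.4)
  i1 <- iccOnewaySingle(a, b)$icc
  i2 <- iccOnewaySingle(3 * a - 10, 3 * b - 10)$icc
  expect_equal(i1, i2, tolerance = 1e-12)
  # two independent raters: ICC within 0.05 of zero at n = 2000
  set.seed(1)
  u <- rnorm(2000); v <- rnorm(2000)
  expect_lt(abs(iccOnewaySingle(u, v)$icc), 0.05)
})

test_that("ICC Monte-Carlo recovery converges to r / (r + 1)", {
  # subject effect with variance ratio r against unit observer noise
  r <- 1.5
  set.seed(21)
  n <- 500
  subj <- rnorm(n, sd = sqrt(r))
  o1 <- subj + rnorm(n); o2 <- subj + rnorm(n)
  expect_lt(abs(iccOnewaySingle(o1, o2)$icc - r / (r + 1)), 0.05)
})

test_that("MAD and SD follow the mean-absolute-difference convention", {
  expect_equal(unname(madSd(c(1, 3), c(2, 5))[["mad"]]), 1.5)
  expect_equal(madSd(1:5, 1:5), c(mad = 0, sd = 0))
  # brute-force loop oracle
  set.seed(2)
  x <- rnorm(25); y <- rnorm(25)
  acc <- 0
  for (i in 1:25) acc <- acc + abs(x[i] - y[i])
  ms <- madSd(x, y)
  expect_equal(unname(ms[["mad"]]), acc / 25)
  expect_equal(unname(ms[["sd"]]), sd(abs(x - y)))
  # symmetry under swapping the observers
  expect_identical(madSd(x, y), madSd(y, x))
  expect_error(madSd(1:3, 1:4), "mismatch")
})

test_that("paired t equals the closed form and rejects degenerate input", {
  # symmetric zero-mean differences: t = 0, p = 1
  a <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  b <- a + c(0.3, -0.3, 0.1, -0.1, 0.2, -0.2, 0.4, -0.4, 0.5, -0.5)
  pt <- pairedT(a, b)
  expect_equal(unname(pt[["t"]]), 0, tolerance = 1e-12)
  expect_equal(unname(pt[["p"]]), 1, tolerance = 1e-12)
  # closed form on differences {1,2,3,4}
  x <- c(2, 4, 6, 8); y <- c(1, 2, 3, 4) # differences 1..4
  pt2 <- pairedT(x, y)
  d <- x - y
  tExp <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(unname(pt2[["t"]]), tExp, tolerance = 1e-12)
  expect_equal(unname(pt2[["p"]]), 2 * pt(-abs(tExp), df = 3),
               tolerance = 1e-12)
  expect_error(pairedT(1, 2), "n >= 2")
  expect_error(pairedT(c(1, 2, 3), c(0, 1, 2)), "zero-variance")
})

test_that("ICC classification follows both conventions, discrepancy visible", {
  expect_equal(classifyIcc(0.95), "excellent")
  expect_equal(classifyIcc(0.3), "poor")
  expect_equal(classifyIcc(0.6), "moderate")
  # the published range treats 0.82 as excellent; the default scale says good
  expect_equal(classifyIcc(0.82), "good")
  expect_equal(classifyIcc(0.82, convention = "published-range"), "excellent")
  expect_error(classifyIcc(NA_real_), "finite")
})

test_that("reliability report aggregates ICC, MAD and method comparisons", {
  set.seed(33)
  cases <- sprintf("c%02d", 1:10)
  df <- expand.grid(case = cases, method = c("surface", "voxel"),
                    observer = c("obs1", "obs2"), region = c("condyle", "R01"),
                    stringsAsFactors = FALSE)
  base <- rnorm(nrow(df), 0.2, 0.05)
  df$distance_mm <- abs(base + ifelse(df$method == "voxel", 0.15, 0) +
                          rnorm(nrow(df), 0, 0.02))
  df$volume_pct <- rnorm(nrow(df), 0, 2)
  rep_ <- reliabilityReport(df)
  expect_setequal(unique(rep_$reliability$region), c("condyle", "R01"))
  expect_true(all(rep_$reliability$n == 10))
  expect_true(all(rep_$reliability$icc >= -1 & rep_$reliability$icc <= 1))
  cmp <- rep_$methodComparison
  expect_true(all(cmp$p > 0 & cmp$p <= 1))
  # the built-in 0.15 mm method offset should surface as significant
  expect_true(all(cmp$p[cmp$quantity == "distance_mm"] < 0.05))
})
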