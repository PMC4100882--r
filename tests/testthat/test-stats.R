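# Through-origin regression, AIC selection, ANCOVA, ANOVA/Tukey,
# correlations. lm() and brute-force permutation serve as independent
# oracles for the hand-rolled pieces.

test_that("exact through-origin fits recover their generating
           coefficients", {
  x <- 1:8
  f1 <- fitThroughOrigin(x, 2 * x, degree = 1)
  expect_equal(unname(f1@coefficients), 2)
  expect_equal(f1@rSquared, 1)
  f2 <- fitThroughOrigin(x, 3 * x^2, degree = 2)
  expect_equal(unname(f2@coefficients), c(0, 3), tolerance = 1e-10)
  expect_equal(f2@rSquared, 1)
  expect_error(fitThroughOrigin(rep(0, 5), 1:5), "all zero")
  expect_error(fitThroughOrigin(1:2, 1:2, degree = 2), "at least")
})

test_that("normal-equation fits agree with lm() and satisfy
           orthogonality", {
  set.seed(11)
  x <- runif(20, 1, 10)
  y <- 1.5 * x + 0.2 * x^2 + rnorm(20)
  f1 <- fitThroughOrigin(x, y, 1)
  f2 <- fitThroughOrigin(x, y, 2)
  # independent oracle: R's own least squares without intercept
  expect_equal(unname(f1@coefficients),
               unname(coef(lm(y ~ 0 + x))), tolerance = 1e-10)
  expect_equal(unname(f2@coefficients),
               unname(coef(lm(y ~ 0 + x + I(x^2)))), tolerance = 1e-10)
  # residuals orthogonal to the basis columns (normal equations)
  res <- y - cbind(x, x^2) %*% f2@coefficients
  expect_lt(abs(sum(res * x)) / sum(abs(y)), 1e-8)
  expect_lt(abs(sum(res * x^2)) / sum(abs(y) * x), 1e-8)
})

test_that("noisy linear coefficients are recovered within 10% across
           replicates", {
  set.seed(99)
  x <- seq(1, 8)
  coefs <- replicate(100, {
    y <- 0.4 * x + rnorm(8, 0, 0.05 * diff(range(0.4 * x)))
    unname(fitThroughOrigin(x, y, 1)@coefficients)
  })
  expect_lt(abs(mean(coefs) - 0.4) / 0.4, 0.02)   # unbiased on average
  expect_gt(mean(abs(coefs - 0.4) / 0.4 < 0.10), 0.90)
})

test_that("AIC selection matches the closed-form selection rate and
           always prefers the smaller model on ties", {
  # equal RSS: the 2-parameter model pays a higher penalty
  x <- c(1, 2, 3, 4); y <- 2 * x
  s <- aicSelect(fitThroughOrigin(x, y, 1), fitThroughOrigin(x, y, 2))
  expect_identical(s$preferred, "linear_origin")
  expect_error(aicSelect(fitThroughOrigin(1:5, 1:5, 1),
                         fitThroughOrigin(1:6, 1:6, 2)), "same data")
  # under a true linear law, the quadratic model wins exactly when
  # F(1, n-2) exceeds (n-2)(exp(2/n)-1); simulation must match that rate
  n <- 12
  thr <- (n - 2) * (exp(2 / n) - 1)
  expectLinear <- pf(thr, 1, n - 2)
  set.seed(202)
  xx <- seq(1, 6, length.out = n)
  picks <- replicate(400, {
    yy <- 0.7 * xx + rnorm(n, 0, 0.3)
    aicSelect(fitThroughOrigin(xx, yy, 1),
              fitThroughOrigin(xx, yy, 2))$preferred == "linear_origin"
  })
  expect_lt(abs(mean(picks) - expectLinear), 0.07) # binomial MC band
  # a clearly convex law is identified essentially always
  picks2 <- replicate(200, {
    yy <- (0.3 * xx + 0.3 * xx^2) * exp(rnorm(n, 0, 0.05))
    aicSelect(fitThroughOrigin(xx, yy, 1),
              fitThroughOrigin(xx, yy, 2))$preferred
  })
  expect_gte(mean(picks2 == "quadratic_origin"), 0.9)
})

test_that("ANCOVA detects different slopes and enforces preconditions", {
  set.seed(5)
  x1 <- runif(10, 0, 10); x2 <- runif(10, 0, 10)
  g1 <- list(x = x1, y = 1 * x1 + rnorm(10, 0, 0.1))
  g3 <- list(x = x2, y = 3 * x2 + rnorm(10, 0, 0.1))
  out <- ancovaSlopes(list(a = g1, b = g3))
  expect_lt(out$p, 0.001)
  expect_error(ancovaSlopes(list(a = g1)), "at least 2")
  expect_error(ancovaSlopes(list(a = g1,
                                 b = list(x = rep(1, 5), y = rnorm(5)))),
               "constant x")
})

test_that("ANCOVA type-I error is near nominal under the null", {
  set.seed(31)
  hits <- replicate(200, {
    x1 <- runif(8, 0, 10); x2 <- runif(8, 0, 10)
    g1 <- list(x = x1, y = 2 * x1 + rnorm(8))
    g2 <- list(x = x2, y = 2 * x2 + rnorm(8))
    ancovaSlopes(list(a = g1, b = g2))$p < 0.05
  })
  expect_lt(abs(mean(hits) - 0.05), 0.045)
})

test_that("one-way ANOVA with Tukey separates a shifted group and
           adjusts p-values upward", {
  expect_equal(anovaTukey(list(a = c(1, 2, 3), b = c(1, 2, 3)))$F, 0)
  expect_equal(anovaTukey(list(a = c(1, 2, 3), b = c(1, 2, 3)))$p, 1)
  base <- c(-1.2, -0.6, -0.2, 0.1, 0.3, 0.5, 0.9, 1.4)
  g <- list(a = base, b = base, c = base + 10 * sd(base))
  out <- anovaTukey(g)
  expect_lt(out$p, 1e-6)
  pw <- out$pairwise
  expect_lt(pw$p_adj[pw$comparison == "c-a"], 0.001)
  expect_lt(pw$p_adj[pw$comparison == "c-b"], 0.001)
  expect_gt(pw$p_adj[pw$comparison == "b-a"], 0.5)
  # Tukey-adjusted p >= unadjusted pooled-sd pairwise p
  raw <- pairwise.t.test(unlist(g), rep(names(g), each = 8),
                         p.adjust.method = "none", pool.sd = TRUE)$p.value
  expect_gte(pw$p_adj[pw$comparison == "b-a"], raw["b", "a"] - 1e-9)
  expect_error(anovaTukey(list(a = 1:3)), "at least 2")
  expect_error(anovaTukey(list(a = 1:3, b = numeric(0))), "at least 2")
})

test_that("ANOVA type-I error is near nominal under the null", {
  set.seed(47)
  hits <- replicate(200, {
    anovaTukey(list(a = rnorm(8), b = rnorm(8), c = rnorm(8)))$p < 0.05
  })
  expect_lt(abs(mean(hits) - 0.05), 0.045)
})

test_that("parametric tests agree with a brute-force permutation oracle
           on a fixed two-group micro-dataset", {
  set.seed(61)
  a <- rnorm(6, 0); b <- rnorm(6, 1)
  vals <- c(a, b)
  # exact enumeration of all 924 assignments of 6-vs-6 labels
  combs <- combn(12, 6)
  fstat <- function(i) {
    x <- vals[i]; y <- vals[-i]
    (6 * (mean(x) - mean(vals))^2 + 6 * (mean(y) - mean(vals))^2) /
      ((sum((x - mean(x))^2) + sum((y - mean(y))^2)) / 10)
  }
  fobs <- fstat(1:6)
  fperm <- apply(combs, 2, fstat)
  pPerm <- mean(fperm >= fobs - 1e-12)
  pParam <- anovaTukey(list(g1 = a, g2 = b))$p
  expect_lt(abs(pParam - pPerm), 0.06)
})

test_that("reproducibility correlations obey exact limits and split by
           group", {
  v <- c(10, 20, 30, 40)
  expect_equal(reproducibilityCorrelation(v, v)$r, 1)
  expect_equal(reproducibilityCorrelation(v, rev(v))$r, -1)
  expect_error(reproducibilityCorrelation(rep(1, 4), v), "variance")
  expect_error(reproducibilityCorrelation(1:2, 1:2), "at least 3")
  set.seed(8)
  first <- runif(16, 100, 500)
  second <- first * exp(rnorm(16, 0, 0.05))
  grp <- rep(c("A", "B", "C", "D"), each = 4)
  out <- reproducibilityCorrelation(first, second, group = grp)
  expect_gt(out$r, 0.95)
  expect_identical(sort(names(out$by_group)), c("A", "B", "C", "D"))
})
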