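test_that("scaled mass index collapses correctly in its algebraic limits", {
  # all SVL at the reference length: SMI is the raw mass
  mass <- c(3.1, 4.0, 3.6, 4.4)
  svl <- rep(60, 4) + c(-1e-9, 1e-9, 0, 0)  # tiny jitter to keep var > 0
  expect_error(scaled_mass_index(mass, rep(60, 4)), "zero variance")
  # exact power law, no scatter: every SMI equals a * L0^b
  set.seed(1)
  L <- runif(30, 45, 75)
  a <- 2e-5; b <- 3.1
  m <- a * L^b
  smi <- scaled_mass_index(m, L)
  L0 <- mean(L)
  expect_equal(unname(as.numeric(smi)), rep(a * L0^b, 30), tolerance = 1e-8)
  expect_equal(attr(smi, "b_sma"), b, tolerance = 1e-8)
})

test_that("SMI geometric mean is invariant to rescaling length units", {
  set.seed(2)
  L <- runif(40, 45, 75)
  m <- 2e-5 * L^3 * exp(rnorm(40, 0, 0.1))
  s_mm <- scaled_mass_index(m, L)                      # mm, L0 = mean
  s_cm <- scaled_mass_index(m, L / 10, L0 = mean(L) / 10)  # cm, same L0 point
  expect_equal(as.numeric(s_mm), as.numeric(s_cm), tolerance = 1e-10)
  expect_equal(attr(s_mm, "b_sma"), attr(s_cm, "b_sma"), tolerance = 1e-10)
})

test_that("AICc matches its closed form and limits", {
  expect_equal(aicc(-7, 3, 10), 24, tolerance = 1e-15)
  expect_equal(aicc(-5, 0, 10), 10)                 # no-parameter limit
  expect_equal(aicc(-5, 2, 1e9), -2 * (-5) + 4, tolerance = 1e-6)  # plain AIC
  expect_error(aicc(-5, 4, 5), "undefined")
})

test_that("model ranking orders by AICc and normalizes Akaike weights", {
  mk <- function(label, ll, k, n) list(label = label, loglik = ll, k = k, n = n)
  one <- rank_models(list(mk("a", -10, 2, 50)))
  expect_equal(one$delta_AICc, 0)
  expect_equal(one$weight, 1)
  # two models with AICc 100 and 102: weights exp(0), exp(-1) normalized
  # AICc = -2 ll + 2k + 2k(k+1)/(n-k-1); solve ll for k=2, n=102 -> corr = 12/99
  corr <- 2 * 2 * 3 / (102 - 3)
  two <- rank_models(list(mk("m1", -(100 - 4 - corr) / 2, 2, 102),
                          mk("m2", -(102 - 4 - corr) / 2, 2, 102)))
  expect_equal(two$AICc, c(100, 102), tolerance = 1e-12)
  expect_equal(two$weight, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  # equal AICc: symmetric weights, tie broken by fewer parameters
  tie <- rank_models(list(mk("big", -10, 4, 60), mk("small", -11.070018, 2, 60)))
  expect_equal(sum(tie$weight), 1, tolerance = 1e-12)
  expect_error(rank_models(list(mk("a", -1, 2, 50), mk("b", -1, 2, 60))),
               "different numbers")
})

test_that("single-group mixed fits equal OLS; zero between-group variance matches lm", {
  set.seed(3)
  n <- 80
  dat <- data.frame(y = rnorm(n), x = rnorm(n),
                    year = rep("2007", n), stringsAsFactors = FALSE)
  dat$y <- 1 + 2 * dat$x + rnorm(n, 0, 0.5)
  fm <- fit_lmm(dat, "y", "x", "year")
  ols <- lm(y ~ x, data = dat)
  expect_equal(unname(fm$coefficients), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(fm$k, 4)  # 2 fixed + 2 variance components
  # several groups but no group effect: coefficients agree with OLS to 1e-6
  dat2 <- dat; dat2$year <- rep(c("2006", "2007", "2008"), length.out = n)
  fm2 <- suppressMessages(fit_lmm(dat2, "y", "x", "year"))
  expect_equal(unname(fm2$coefficients), unname(coef(ols)), tolerance = 1e-6)
  # nesting: adding a term never lowers the ML log-likelihood
  fm0 <- suppressMessages(fit_lmm(dat2, "y", character(0), "year"))
  expect_gte(fm2$loglik + 1e-8, fm0$loglik)
  # singular designs are named
  dat2$x2 <- dat2$x
  expect_error(suppressMessages(fit_lmm(dat2, "y", c("x", "x2"), "year")),
               "singular|collinear")
})

test_that("mixed-model slopes recover generating effects within 2 SE (simulation)", {
  hits <- 0
  for (s in 1:25) {
    set.seed(400 + s)
    n <- 120
    year <- sample(c("2006", "2007", "2008"), n, replace = TRUE)
    u <- c("2006" = 0.3, "2007" = -0.1, "2008" = 0.2)
    x <- runif(n, 0, 10)
    y <- 2 + 0.5 * x + u[year] + rnorm(n, 0, 0.8)
    fm <- suppressMessages(fit_lmm(data.frame(y = y, x = x, year = year),
                                   "y", "x", "year"))
    se <- sqrt(diag(as.matrix(vcov(fm$fit))))[2]
    if (abs(fm$coefficients[["x"]] - 0.5) <= 2 * se) hits <- hits + 1
  }
  expect_gte(hits, 22)
})

test_that("linear regression reproduces closed-form normal equations", {
  r <- suppressWarnings(linear_regression(2 * (1:10) + 1, 1:10))
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$intercept, 1, tolerance = 1e-12)
  expect_equal(r$r_squared, 1)
  # fixed 5-point set vs hand-computed least squares
  x <- c(1, 2, 4, 5, 7); y <- c(2.1, 2.9, 5.2, 5.8, 8.3)
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  inter_hand <- mean(y) - slope_hand * mean(x)
  r2 <- linear_regression(y, x)
  expect_equal(r2$slope, slope_hand, tolerance = 1e-12)
  expect_equal(r2$intercept, inter_hand, tolerance = 1e-12)
  set.seed(5)
  r3 <- linear_regression(rnorm(500), rnorm(500))
  expect_lt(r3$r_squared, 0.05)
  expect_error(linear_regression(1:5, rep(2, 5)), "slope undefined")
})

test_that("signed-rank test reproduces exact enumeration p-values", {
  # n = 6, all differences positive: most extreme of 2^6 sign patterns
  # (differences kept distinct so the exact enumeration null applies)
  a6 <- c(5, 6, 7, 8, 9, 10); b6 <- c(1, 2.2, 2.5, 3, 3.5, 4)
  r6 <- paired_signed_rank(a6, b6)
  expect_equal(r6$p_value, 2 / 64, tolerance = 1e-12)
  expect_equal(r6$method, "exact")
  # n = 5, all positive
  r5 <- paired_signed_rank(a6[1:5], b6[1:5])
  expect_equal(r5$p_value, 2 / 32, tolerance = 1e-12)
  # swapping a and b mirrors the statistic, same p
  r6s <- paired_signed_rank(b6, a6)
  expect_equal(r6s$p_value, r6$p_value)
  expect_equal(r6s$statistic, 6 * 7 / 2 - r6$statistic)
  expect_error(paired_signed_rank(1:4, 1:4), "degenerate")
})

test_that("rank-sum test reproduces exact enumeration and symmetry", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 2 / 20, tolerance = 1e-12)  # 2 of C(6,3) orderings
  expect_equal(r$method, "exact")
  expect_equal(r$statistic, 0)  # W for the low group
  rs <- rank_sum_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rs$statistic, 9)  # complementary statistic
  expect_equal(rs$p_value, r$p_value)
  ri <- rank_sum_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gte(ri$p_value, 0.99)
  expect_error(rank_sum_test(numeric(0), 1:3), "nonempty")
})

test_that("Kruskal-Wallis has the right df and agrees with rank-sum for 2 groups", {
  set.seed(7)
  vals <- rnorm(40)
  g4 <- rep(letters[1:4], each = 10)
  k4 <- kruskal_wallis(vals, g4)
  expect_equal(k4$df, 3)
  # all values identical: H = 0, p = 1 by convention
  kc <- kruskal_wallis(rep(1, 12), rep(letters[1:3], each = 4))
  expect_equal(kc$H, 0)
  expect_equal(kc$p_value, 1)
  expect_error(kruskal_wallis(vals, rep("a", 40)), "two groups")
  # two-group case: H is the chi-square version of the rank-sum z (monotone link)
  a <- rnorm(15); b <- rnorm(15) + 1
  k2 <- kruskal_wallis(c(a, b), rep(c("a", "b"), each = 15))
  w2 <- rank_sum_test(a, b)
  expect_equal(k2$p_value, stats::pchisq(k2$H, 1, lower.tail = FALSE))
  expect_lt(abs(k2$p_value - w2$p_value), 0.02)  # continuity correction only
})

test_that("Tukey pairwise contrasts reduce to a t-test for two groups and stay near 1 under identity", {
  set.seed(8)
  v <- c(rnorm(12), rnorm(12) + 0.5)
  g <- rep(c("x", "y"), each = 12)
  pc <- pairwise_contrasts(v, g)
  tt <- t.test(v[g == "y"], v[g == "x"], var.equal = TRUE)
  expect_equal(pc$p_adjusted, tt$p.value, tolerance = 1e-6)
  expect_equal(pc$estimate, unname(diff(tapply(v, g, mean))), tolerance = 1e-10)
  # three identical groups
  base <- rnorm(10)
  pc3 <- pairwise_contrasts(rep(base, 3), rep(c("a", "b", "c"), each = 10))
  expect_true(all(pc3$p_adjusted > 0.99))
  expect_true(all(abs(pc3$estimate) < 1e-12))
  # a group with < 2 observations is skipped, not silently dropped
  pc_sk <- pairwise_contrasts(c(rnorm(10), rnorm(10), 1),
                              c(rep("a", 10), rep("b", 10), "c"))
  expect_true(any(pc_sk$skipped))
  expect_true(all(!pc_sk$skipped[grepl("^b - a|^a - b", pc_sk$pair)]))
})

test_that("a shifted group is detected by its two pairs only (simulation)", {
  detections <- 0; false_hits <- 0; runs <- 40
  for (s in 1:runs) {
    set.seed(900 + s)
    v <- c(rnorm(15), rnorm(15), rnorm(15) + 1.6)
    g <- rep(c("a", "b", "c"), each = 15)
    pc <- pairwise_contrasts(v, g)
    pc_c <- pc[grepl("c", pc$pair), ]
    pc_ab <- pc[!grepl("c", pc$pair), ]
    if (all(pc_c$p_adjusted < 0.05)) detections <- detections + 1
    if (any(pc_ab$p_adjusted < 0.05)) false_hits <- false_hits + 1
  }
  expect_gte(detections, 0.9 * runs)
  expect_lte(false_hits, 0.2 * runs)
})
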