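test_that("latin hypercube draws stratify every marginal exactly", {
  set.seed(1)
  d <- lhs_sample(list(a = c(0, 1), b = c(10, 30)), 4)
  expect_identical(dim(d), c(4L, 2L))
  strata <- findInterval(sort(d[, "a"]), c(0, 0.25, 0.5, 0.75, 1),
                         rightmost.closed = TRUE)
  expect_identical(strata, 1:4)
  strata_b <- findInterval(sort(d[, "b"]), seq(10, 30, 5), rightmost.closed = TRUE)
  expect_identical(strata_b, 1:4)
  # one draw in every one of n strata at larger n
  set.seed(2)
  n <- 50
  x <- lhs_sample(list(p = c(-2, 2)), n)[, 1]
  expect_identical(sort(findInterval(x, seq(-2, 2, length.out = n + 1),
                                     rightmost.closed = TRUE)), 1:n)
})

test_that("degenerate and tabulated ranges are honored", {
  set.seed(3)
  d <- lhs_sample(list(fixed = c(5, 5), M_star_p = c(0.0016, 0.0465)), 20)
  expect_true(all(d[, "fixed"] == 5))
  expect_true(all(d[, "M_star_p"] >= 0.0016 & d[, "M_star_p"] <= 0.0465))
  expect_error(lhs_sample(list(bad = c(2, 1)), 5), "min > max")
})

test_that("marginals pass a chi-square uniformity check at n = 1000", {
  set.seed(4)
  x <- lhs_sample(default_param_ranges(c("r", "S")), 1000)
  for (col in colnames(x)) {
    rng <- default_param_ranges(col)[[1]]
    counts <- table(cut(x[, col], breaks = seq(rng[1], rng[2], length.out = 21),
                        include.lowest = TRUE))
    expect_gt(stats::chisq.test(counts)$p.value, 0.01)
  }
})

test_that("batches are reproducible and record per-run outcomes", {
  fx <- make_fixture_scenario("warm")
  set.seed(5)
  design <- lhs_sample(fx$config$ranges, 10)
  b1 <- run_batch(fx$config, fx$temps, design, base_seed = 42)
  b2 <- run_batch(fx$config, fx$temps, design, base_seed = 42)
  expect_identical(b1$t_e, b2$t_e)
  expect_identical(nrow(b1), 10L)
  expect_true(all(b1$terminated_by %in% c("EXTIRPATED", "TEMPS_EXHAUSTED")))
  expect_true(all(b1$seed == 42 + 1:10))
})

test_that("lethal parameters extirpate within a day", {
  fx <- make_fixture_scenario("warm")
  design <- lhs_sample(fx$config$ranges, 3)
  design[, grep("^M_star_", colnames(design))] <- 1
  b <- run_batch(fx$config, fx$temps, design, base_seed = 9)
  expect_true(all(b$t_e <= 1))
})

test_that("extirpation statistics handle censoring and quantiles", {
  b <- data.frame(t_e = c(100, 200), terminated_by = rep("EXTIRPATED", 2))
  st <- extirpation_stats(b, q = 0.95)
  expect_equal(st$t_m, 150)
  expect_equal(st$t_q, 200)
  ball <- data.frame(t_e = rep(120, 5), terminated_by = "EXTIRPATED")
  st2 <- extirpation_stats(ball)
  expect_equal(st2$t_m, 120); expect_equal(st2$t_q, 120)
  # censored runs count as not-yet-extirpated
  bc <- data.frame(t_e = c(10, 20, NA, NA), terminated_by =
                     c("EXTIRPATED", "EXTIRPATED", "TEMPS_EXHAUSTED",
                       "TEMPS_EXHAUSTED"))
  expect_true(is.na(extirpation_stats(bc, q = 0.95)$t_q))
  expect_equal(extirpation_stats(bc, q = 0.5)$t_q, 20)
  expect_error(extirpation_stats(data.frame(t_e = NA,
                                            terminated_by = "TEMPS_EXHAUSTED")),
               "no extirpated")
  # q = 0 returns the minimum; quantiles are monotone in q
  set.seed(6)
  bu <- data.frame(t_e = sample(1:365, 1e4, replace = TRUE),
                   terminated_by = "EXTIRPATED")
  expect_equal(extirpation_stats(bu, q = 0)$t_q, min(bu$t_e))
  qs <- vapply(c(0.1, 0.5, 0.9, 0.95), function(q) extirpation_stats(bu, q)$t_q, 0)
  expect_true(all(diff(qs) >= 0))
  # order-statistics oracle for the 95 % quantile of Uniform{1..365}
  expect_lt(abs(extirpation_stats(bu, q = 0.95)$t_q - 347), 3)
})

# brute-force partial correlation of ranks via the precision matrix
prcc_oracle <- function(X, y) {
  M <- cbind(apply(X, 2, rank), rank(y))
  P <- solve(stats::cor(M))
  k <- ncol(X)
  vapply(seq_len(k), function(j) -P[j, k + 1] / sqrt(P[j, j] * P[k + 1, k + 1]), 0)
}

test_that("PRCC recovers exact monotone association and matches the oracle", {
  set.seed(7)
  X <- matrix(runif(300 * 4), 300, 4, dimnames = list(NULL, paste0("x", 1:4)))
  pr <- prcc(X, X[, 1])
  expect_equal(pr$coefficient[pr$parameter == "x1"], 1, tolerance = 1e-6)
  expect_true(all(abs(pr$coefficient[pr$parameter != "x1"]) < 0.2))

  set.seed(8)
  X <- matrix(runif(500 * 5), 500, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- 2 * X[, 1] - X[, 2] + rnorm(500, 0, 0.3)
  pr <- prcc(X, y)
  orc <- prcc_oracle(X, y)
  got <- pr$coefficient[match(paste0("x", 1:5), pr$parameter)]
  expect_equal(got, orc, tolerance = 1e-6)
  expect_gt(got[1], 0); expect_lt(got[2], 0)
})

test_that("PRCC is invariant to monotone transforms and flags constants", {
  set.seed(9)
  X <- matrix(runif(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1] + 0.5 * X[, 2] + rnorm(200, 0, 0.2)
  p1 <- prcc(X, y)
  X2 <- X; X2[, 1] <- exp(5 * X2[, 1]); X2[, 3] <- -1 / (1 + X2[, 3])
  p2 <- prcc(X2, y)
  expect_equal(p1$coefficient, p2$coefficient, tolerance = 1e-12)

  Xc <- cbind(X, d = 1)
  pc <- prcc(Xc, y)
  expect_true(is.na(pc$coefficient[pc$parameter == "d"]))
  expect_match(pc$note[pc$parameter == "d"], "constant")
})

test_that("the PRCC test statistic follows the published formula", {
  expect_equal(prcc_statistic(-0.60, 10000, 15), -0.6 * sqrt(9983 / 0.64),
               tolerance = 1e-12)
  expect_equal(prcc_statistic(-0.60, 10000, 15), -74.93, tolerance = 1e-2)
  # statistic and p returned by prcc() agree with the formula
  set.seed(10)
  X <- matrix(runif(100 * 3), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1] + rnorm(100, 0, 0.5)
  pr <- prcc(X, y)
  i <- which(pr$parameter == "a")
  expect_equal(pr$statistic[i], prcc_statistic(pr$coefficient[i], 100, 2),
               tolerance = 1e-12)
  expect_equal(pr$p[i], 2 * stats::pt(-abs(pr$statistic[i]), 100 - 2 - 2),
               tolerance = 1e-12)
})

test_that("degree-day quarantine length accumulates to the target day", {
  expect_equal(degree_day_quarantine_length(rep(26, 24 * 80), 12, 340, 3), 73)
  # no accumulation at the base temperature: never reached
  ql <- degree_day_quarantine_length(rep(12, 24 * 50), 12, 340, 3)
  expect_true(is.na(ql))
  expect_true(attr(ql, "not_reached"))
  # linear in the generation count (up to day rounding)
  one <- degree_day_quarantine_length(rep(26, 24 * 80), 12, 340, 1)
  two <- degree_day_quarantine_length(rep(26, 24 * 80), 12, 340, 2)
  expect_lte(abs(two - 2 * one), 1)
  expect_error(degree_day_quarantine_length(rep(26, 24), 12, 0, 3), "K_generation")
})
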