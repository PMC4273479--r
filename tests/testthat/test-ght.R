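test_that("total-read adjustment rescales the raw depth ratio", {
  expect_equal(adjusted_ratio(20, 10, 2e6, 1e6), 1)
  expect_equal(adjusted_ratio(15, 10, 1e6, 1e6), 1.5)
  expect_equal(adjusted_ratio(10, 10, 5e5, 5e5), 1)
  expect_error(adjusted_ratio(5, 0, 1, 1), "positive")
  expect_error(adjusted_ratio(5, 5, 0, 1), "positive")
})

test_that("the GHT statistic matches its closed form and is monotone in r", {
  expect_equal(ght_t(1, 10, 10), 0)
  # independent arithmetic oracle for r = 1.2, lambda = 100:
  # numerator 100*1.2 - 100 = 20, denominator sqrt(100*1.44 + 100)
  expect_equal(ght_t(1.2, 100, 100), 20 / sqrt(244))
  expect_equal(ght_t(1.2, 100, 100), 1.2803688, tolerance = 1e-7)

  r_grid <- seq(0.2, 5, by = 0.01)
  for (lam in list(c(50, 50), c(100, 80), c(500, 900))) {
    t_vals <- ght_t(r_grid, lam[1], lam[2])
    expect_true(all(diff(t_vals) > 0))
  }
  expect_error(ght_t(1, -1, 10), "positive")
})

test_that("two-sided p-values follow the normal tail in the direction of r", {
  expect_equal(two_sided_p(0, 2), 1)
  expect_equal(two_sided_p(0, 1), 1)
  # high-precision erf oracle for Phi
  skip_if_not_installed("pracma")
  phi <- function(t) 0.5 * (1 + pracma::erf(t / sqrt(2)))
  expect_equal(two_sided_p(1.6449, 1.5), 2 * (1 - phi(1.6449)), tolerance = 1e-12)
  expect_equal(two_sided_p(1.6449, 1.5), 0.1000, tolerance = 1e-4)

  t <- seq(-3, 3, by = 0.25)
  expect_equal(two_sided_p(t, rep(2, length(t))),
               two_sided_p(-t, rep(0.5, length(t))))
})

test_that("window calls chain ratio, GHT and p-value correctly", {
  # r = 1.4, t = 40/sqrt(296), p = 2(1 - Phi(t)) -> gain at alpha 0.05
  test <- profile_with_depth(c(140L, rep(100L, 59)))
  control <- profile_with_depth(rep(100L, 60))
  # equalize totals so the adjustment factor is exactly 1
  test$depth[2] <- 60L
  calls <- call_localized(test, control)
  expect_equal(total_reads(test), total_reads(control))
  i <- 1
  expect_equal(calls$r[i], 1.4)
  lam_t <- mean(test$depth)
  lam_c <- 100
  expect_equal(calls$t[i], (lam_c * 1.4 - lam_t) / sqrt(lam_c * 1.4^2 + lam_t))
  expect_equal(calls$p[i], 2 * pnorm(calls$t[i], lower.tail = FALSE))

  # same counts everywhere: r = 1 is neutral by definition
  same <- call_localized(control, control)
  expect_true(all(same$state == "neutral"))
  expect_true(all(same$p == 1))
})

test_that("the textbook chain example yields a gain call", {
  # lambdas 100/100, equal totals, R_t = 140 vs R_c = 100
  t_val <- ght_t(1.4, 100, 100)
  expect_equal(t_val, 40 / sqrt(296))
  expect_equal(t_val, 2.3249528, tolerance = 1e-7)
  p <- two_sided_p(t_val, 1.4)
  expect_equal(p, 0.0200745, tolerance = 1e-6)
  expect_true(p < 0.05)
})

test_that("excluded windows are reported with a reason", {
  test <- profile_with_depth(c(5L, 0L, 5L, 0L))
  control <- profile_with_depth(c(5L, 5L, 0L, 0L))
  calls <- call_localized(test, control)
  excl <- attr(calls, "excluded")
  expect_equal(nrow(calls), 1)
  expect_equal(excl$reason,
               c("zero depth in test", "zero depth in control",
                 "zero depth in both"))
})

test_that("increasing the test depth never flips gain to loss", {
  control <- profile_with_depth(rep(100L, 200))
  states <- character(0)
  for (d in c(40L, 70L, 100L, 130L, 180L)) {
    test <- control
    test$depth[1] <- d
    calls <- call_localized(test, control)
    states <- c(states, as.character(calls$state[1]))
  }
  ord <- c(loss = 1, neutral = 2, gain = 3)
  expect_true(all(diff(ord[states]) >= 0))
})

test_that("GC-grouped calling reduces to global calling when groups share rates", {
  set.seed(21)
  gc <- runif(400, 0.30, 0.60)
  depth_t <- rpois(400, 100) + 1L
  depth_c <- rpois(400, 100) + 1L
  test <- profile_with_depth(depth_t, gc = gc)
  control <- profile_with_depth(depth_c, gc = gc)
  plain <- call_localized(test, control)
  gc_calls <- suppressWarnings(call_localized(test, control, gc_correct = TRUE,
                                              min_group_size = 1e9))
  # with every group falling back to global rates, t is unchanged
  expect_equal(gc_calls$t, plain$t)

  # a window's statistic uses only the rates of its own GC group
  gc2 <- rep(c(0.32, 0.57), each = 4)
  t2 <- profile_with_depth(rep(c(50L, 100L), each = 4), gc = gc2)
  c2 <- profile_with_depth(rep(c(50L, 100L), each = 4), gc = gc2)
  calls2 <- call_localized(t2, c2, gc_correct = TRUE, min_group_size = 2)
  expect_equal(calls2$t, ght_t(calls2$r, rep(c(50, 100), each = 4),
                               rep(c(50, 100), each = 4)))
})

test_that("null simulation yields approximately nominal call rate", {
  n <- 20000
  set.seed(1234)
  w <- make_windows(c(chr1 = n * 5000), 5000)
  test <- dplyr::mutate(w, depth = rpois(n, 100))
  control <- dplyr::mutate(w, depth = rpois(n, 100))
  calls <- call_localized(test, control)
  frac <- mean(calls$state != "neutral")
  se <- sqrt(0.05 * 0.95 / nrow(calls))
  expect_lt(abs(frac - 0.05), 4 * se)
})

test_that("an injected two-fold region is called gain with high power", {
  n <- 2000
  set.seed(99)
  w <- make_windows(c(chr1 = n * 5000), 5000)
  region <- 501:520
  lam <- rep(100, n)
  lam[region] <- 200
  test <- dplyr::mutate(w, depth = rpois(n, lam))
  control <- dplyr::mutate(w, depth = rpois(n, 100))
  calls <- call_localized(test, control)
  expect_gte(mean(calls$state[region] == "gain"), 0.99)
})
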