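test_that("step pairing aligns on first contact and drops spurious steps", {
  tt <- c(1.0, 1.55, 2.1, 2.66)
  L <- c(0.6, 0.62, 0.59, 0.61)
  p <- pair_steps(tt, L, tt, L)
  expect_equal(nrow(p), 4L)
  expect_equal(attr(p, "n_unmatched_est"), 0L)
  expect_equal(p$est, p$ref)

  # global shift is absorbed by first-contact alignment
  p2 <- pair_steps(tt + 0.05, L, tt, L + 0.01)
  expect_equal(nrow(p2), 4L)
  expect_equal(p2$ref, L + 0.01)

  # an interpolated spurious step stays unmatched
  est_t <- c(1.0, 1.3, 1.55, 2.1, 2.66)
  est_L <- c(0.6, 0.2, 0.62, 0.59, 0.61)
  p3 <- pair_steps(est_t, est_L, tt, L)
  expect_equal(nrow(p3), 4L)
  expect_equal(attr(p3, "n_unmatched_est"), 1L)
  expect_false(0.2 %in% p3$est)

  expect_error(pair_steps(numeric(0), numeric(0), tt, L), "empty")
})

test_that("error definitions follow their printed forms", {
  expect_equal(absolute_error(0.60, 0.60), 0)
  expect_equal(absolute_error(0.60, 0.55), 0.05)
  expect_equal(median(abs(absolute_error(c(0.61, 0.63, 0.65),
                                         c(0.60, 0.60, 0.60)))), 0.03)
  expect_equal(percent_error(1.00, 1.05), 5)
  expect_equal(percent_error(0.73, 0.73), 0)
  expect_equal(percent_error(0.50, 0.45), -10)
  expect_error(percent_error(0, 1), "zero")
})

test_that("Bland-Altman matches hand-computed fixtures", {
  mk <- function(d) {
    p <- data.frame(est = 0.6 + d, ref = rep(0.6, length(d)))
    class(p) <- c("paired_steps", "data.frame"); p
  }
  ba0 <- bland_altman(mk(c(0, 0, 0)))
  expect_equal(ba0$bias, 0); expect_equal(ba0$loa_lo, 0); expect_equal(ba0$loa_hi, 0)

  d <- c(0.01, -0.01, 0.01, -0.01)
  ba <- bland_altman(mk(d))
  s <- sd(d)
  expect_equal(ba$bias, 0, tolerance = 1e-15)
  expect_equal(ba$loa_hi, 1.96 * s, tolerance = 1e-12)
  expect_equal(ba$loa_lo, -1.96 * s, tolerance = 1e-12)
  expect_equal(ba$bias_ci_hi, 1.96 * s / 2, tolerance = 1e-12)

  bac <- bland_altman(mk(rep(0.02, 5)))
  expect_equal(bac$bias, 0.02)
  expect_equal(bac$loa_hi - bac$loa_lo, 0)

  # bias is exactly the difference of means
  set.seed(20)
  p <- mk(rnorm(40, 0.005, 0.02))
  expect_lt(abs(bland_altman(p)$bias - (mean(p$est) - mean(p$ref))), 1e-12)

  expect_error(bland_altman(mk(c(0, 0))), "insufficient")
})

test_that("limits of agreement cover ~95% of normal differences", {
  set.seed(21)
  p <- data.frame(est = 0.6 + rnorm(10000, 0.005, 0.02), ref = 0.6)
  ba <- bland_altman(p)
  d <- p$est - p$ref
  cover <- mean(d >= ba$loa_lo & d <= ba$loa_hi)
  expect_gte(cover, 0.93)
})

test_that("correlation and regression match closed forms", {
  ref <- seq(0.4, 0.8, by = 0.05)
  p <- data.frame(est = ref, ref = ref)
  cr <- correlation_regression(p)
  expect_equal(cr$r, 1); expect_equal(cr$slope, 1, tolerance = 1e-12)
  expect_equal(cr$intercept, 0, tolerance = 1e-12)
  expect_equal(cr$r2, cr$r^2, tolerance = 1e-15)

  cr2 <- correlation_regression(data.frame(est = 2 * ref, ref = ref))
  expect_equal(cr2$r, 1); expect_equal(cr2$slope, 2, tolerance = 1e-12)

  cr3 <- correlation_regression(data.frame(est = -ref + 1, ref = ref))
  expect_equal(cr3$r, -1)

  expect_error(correlation_regression(data.frame(est = ref, ref = rep(0.6, 9))),
               "variance")
})

test_that("normality screening distinguishes known error distributions", {
  normal_reject <- heavy_reject <- logical(50)
  for (i in 1:50) {
    set.seed(1000 + i)
    en <- rnorm(200, 0, 0.02)
    eh <- c(rnorm(180, 0, 0.005), rt(20, df = 1) * 0.05)
    pn <- data.frame(est = 0.6 + en, ref = 0.6)
    ph <- data.frame(est = 0.6 + eh, ref = 0.6)
    normal_reject[i] <- nonparametric_tests(pn)$shapiro_p < 0.05
    heavy_reject[i] <- nonparametric_tests(ph)$shapiro_p < 0.05
  }
  expect_gte(mean(!normal_reject), 0.90)
  expect_gte(mean(heavy_reject), 0.90)

  # all-zero differences make the signed-rank test degenerate
  pz <- data.frame(est = rep(0.6, 10), ref = rep(0.6, 10))
  expect_true(nonparametric_tests(pz)$degenerate)
  expect_error(nonparametric_tests(pz[1:5, ]), "insufficient")
})

test_that("group report computes grand medians over subject medians", {
  mk <- function(med, n = 9) {
    p <- data.frame(est = 0.6 + med + seq(-0.004, 0.004, length.out = n),
                    ref = 0.6, side = rep(c("left", "right"), length.out = n))
    class(p) <- c("paired_steps", "data.frame"); p
  }
  one <- group_report(list(A = mk(0.03)))
  expect_equal(unique(one$grand$mdae), unique(one$per_subject$mdae))

  gr <- group_report(list(A = mk(0.02), B = mk(0.03), C = mk(0.04)))
  expect_equal(sort(unique(gr$grand$side)), c("left", "right"))
  left <- gr$per_subject[gr$per_subject$side == "left", ]
  expect_equal(gr$grand$mdae[gr$grand$side == "left"], median(left$mdae))

  # invariant to subject ordering
  gr2 <- group_report(list(C = mk(0.04), A = mk(0.02), B = mk(0.03)))
  expect_equal(gr$grand$mdae, gr2$grand$mdae)
})

test_that("the pooled agreement report is internally consistent", {
  set.seed(22)
  ref <- runif(60, 0.4, 0.8)
  p <- data.frame(est = ref + rnorm(60, 0.002, 0.01), ref = ref)
  rep <- agreement_report(p)
  expect_equal(rep$r2, rep$r^2, tolerance = 1e-15)
  expect_true(rep$loa_lo < rep$bias && rep$bias < rep$loa_hi)
  expect_true(rep$iqr_lo <= rep$mdae && rep$mdae <= rep$iqr_hi)
  expect_equal(rep$n, 60L)
})
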