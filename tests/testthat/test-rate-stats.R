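make_curve <- function(time, loop, sg_window = 50) {
  d <- data.frame(time_s = time, loop_kbp = loop)
  suppressWarnings(loop_growth_curve(d, sg_window = sg_window))
}

test_that("growth curve smoothing shrinks over-long windows with warning", {
  d <- data.frame(time_s = 1:20, loop_kbp = (1:20) * 0.5)
  expect_warning(cv <- loop_growth_curve(d), "Savitzky-Golay")
  expect_equal(attr(cv, "sg_window"), 19L)
  expect_equal(nrow(cv), 20L)
  expect_equal(length(cv$smoothed_kbp), length(cv$loop_kbp))
})

test_that("an even smoothing window is rounded down to odd", {
  d <- data.frame(time_s = 1:60, loop_kbp = (1:60) * 0.5)
  cv <- loop_growth_curve(d, sg_window = 50)
  expect_equal(attr(cv, "sg_window"), 49L)
})

test_that("fit window starts at initiation on noiseless linear growth", {
  t <- 10:30
  cv <- make_curve(t, (t - 10) * 1.0)
  expect_equal(choose_fit_window(cv), c(10, 15))
})

test_that("slip-back pushes the window past the slip", {
  t <- 1:40
  loop <- c(rep(0, 9),                     # pre-initiation
            5, 6, 7,                       # growth from t = 10
            6, 5, 4, 3, 2, 1, 0,           # slip back over t = 13..19
            seq(1, 21, by = 1))            # regrowth from t = 20
  # short smoothing window so the slip survives smoothing on a 40-pt curve
  cv <- make_curve(t, loop, sg_window = 9)
  w <- choose_fit_window(cv)
  # every window straddling the steep slip (starts 10..17) is rejected;
  # the accepted start sits at the smoothed slip bottom, where only the
  # shallow (<0.5 kbp) smoothed tail of the decline remains
  expect_gte(w[1], 18)
  expect_lt(abs(fit_rate(cv, c(20, 25))$k - 1), 1e-9)
})

test_that("a flat curve yields the exclusion error", {
  cv <- make_curve(1:20, rep(3, 20))
  expect_error(choose_fit_window(cv), class = "loopx_no_monotone_window")
})

test_that("rate fit recovers an exact line and rejects 2-point input", {
  t <- seq(0, 10, by = 0.5)
  cv <- make_curve(t, 1.2 * t + 0.5)
  r <- fit_rate(cv, c(2, 7))
  expect_equal(r$k, 1.2, tolerance = 1e-12)
  expect_equal(r$c, 0.5, tolerance = 1e-12)
  expect_equal(r$r_squared, 1)
  expect_error(fit_rate(cv, c(0, 0.5)), class = "loopx_too_few_points")
})

test_that("the rate fit uses raw data, not the smoothed curve", {
  t <- 1:30
  cv <- make_curve(t, 0.8 * t)
  w <- choose_fit_window(cv)
  corrupted <- cv
  corrupted$smoothed_kbp <- rev(cv$smoothed_kbp)  # break the smoother
  expect_equal(fit_rate(corrupted, w)$k, fit_rate(cv, w)$k)
  expect_equal(fit_rate(corrupted, w)$k, 0.8, tolerance = 1e-12)
})

test_that("fraction_looped counts and is order-invariant", {
  x <- c(rep(TRUE, 24), FALSE)
  s <- fraction_looped(x)
  expect_equal(s$fraction_looped, 0.96)
  expect_equal(s$n_tethers, 25L)
  expect_equal(fraction_looped(rep(FALSE, 7))$fraction_looped, 0)
  expect_equal(fraction_looped(c(rep(TRUE, 6), rep(FALSE, 19)))$fraction_looped,
               0.24)
  set.seed(1)
  expect_equal(fraction_looped(sample(x))$fraction_looped,
               s$fraction_looped)
  expect_error(fraction_looped(logical(0)), class = "loopx_empty_group")
})

test_that("rank-sum: symmetric identical groups give p = 1", {
  r <- ranksum_test(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(r$p_value, 1)
})

test_that("rank-sum: fully separated 3 vs 3 gives the exact floor p = 0.1", {
  r <- ranksum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 6)
  expect_equal(r$p_value, 0.1)
})

test_that("rank-sum p is invariant to adding a constant", {
  set.seed(2)
  x <- runif(4); y <- runif(5)
  expect_equal(ranksum_test(x + 100, y + 100)$p_value,
               ranksum_test(x, y)$p_value)
})

test_that("exact rank-sum matches wilcox.test enumeration for all n <= 8", {
  set.seed(3)
  for (n1 in 1:4) for (n2 in n1:(8 - n1)) {
    for (rep in 1:3) {
      x <- round(runif(n1), 3); y <- round(runif(n2), 3)  # tie-free w.h.p.
      if (anyDuplicated(c(x, y))) next
      ours <- ranksum_test(x, y)
      ref <- wilcox.test(x, y, exact = TRUE)
      # wilcox.test reports U = W - n1(n1+1)/2
      expect_equal(ours$statistic - n1 * (n1 + 1) / 2,
                   unname(ref$statistic))
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("large-sample rank-sum matches the tie-corrected normal approx", {
  set.seed(4)
  x <- sample(1:8, 12, replace = TRUE)
  y <- sample(3:10, 11, replace = TRUE)
  ours <- ranksum_test(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("Welch t: identical groups give t = 0, p = 1", {
  r <- compare_rates(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("Welch t matches the closed form and t.test", {
  x <- c(10, 12, 14); y <- c(20, 26, 32)
  r <- welch_t(x, y)
  se <- sqrt(var(x) / 3 + var(y) / 3)
  t_hand <- (mean(x) - mean(y)) / se
  df_hand <- se^4 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  expect_equal(r$statistic, t_hand)
  expect_equal(r$df, df_hand)
  expect_equal(r$p_value, 2 * pt(-abs(t_hand), df_hand))
})

test_that("Welch df is below the pooled df for unequal variances", {
  x <- c(1, 2, 3); y <- c(1, 2, 3, 100)
  expect_lt(welch_t(x, y)$df, length(x) + length(y) - 2)
})

test_that("recovery holds across slow and fast ground-truth rates", {
  for (rate in c(0.5, 2.0)) {
    ks <- vapply(1:8, function(s) {
      res <- sim_and_quantify(500 + s,
                              events = list(std_loop_event(rate = rate)))
      if (!res$q$looped || is.null(res$q$dna)) return(NA_real_)
      re <- suppressWarnings(estimate_loop_rate(res$q$dna))
      if (inherits(re, "rate_estimate")) re$k else NA_real_
    }, numeric(1))
    expect_gt(sum(!is.na(ks)), 5)
    expect_lte(median(abs(ks - rate) / rate, na.rm = TRUE), 0.10)
  }
})

test_that("zero-variance degenerate groups raise an explicit error", {
  expect_error(welch_t(c(0, 0), c(1, 1)),
               class = "loopx_degenerate_groups")
  expect_error(compare_rates(list(c(1), c(1, 2))),
               class = "loopx_empty_group")
  expect_error(compare_fractions(list(numeric(0), c(1))),
               class = "loopx_empty_group")
})
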