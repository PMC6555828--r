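# Base-10 log-normal mixture decomposition of FACS fluorescence.

test_that("single log-normal fit is the ML estimate on log10 values", {
  f <- fit_lognormal(c(10, 1000))
  expect_equal(f$mu, 2)
  expect_equal(f$sigma, 1)
  deg <- fit_lognormal(c(100, 100, 100))
  expect_equal(deg$mu, 2)
  expect_equal(deg$sigma, 0)
  expect_true(deg$degenerate)
  expect_error(fit_lognormal(c(-1, 5, 10)), "nonpositive")
  expect_error(fit_lognormal(100), "at least 2")
})

test_that("drop_nonpositive removes and counts offending values", {
  v <- drop_nonpositive(c(-3, 0, 5, 10, NA), quiet = TRUE)
  expect_equal(as.numeric(v), c(5, 10))
  expect_equal(attr(v, "n_dropped"), 3)
})

test_that("resting-population fit recovers the generating parameters", {
  spec <- facs_reference_specs(seed = 41)$rest
  f <- fit_lognormal(gen_fluorescence(spec))
  se_mu <- 0.21 / sqrt(15000)
  expect_lt(abs(f$mu - 2.06), 3 * se_mu)
  expect_lt(abs(f$sigma - 0.21), 3 * 0.21 / sqrt(2 * 15000))
})

test_that("two-component EM decomposes stimulated populations", {
  specs <- facs_reference_specs(seed = 43)
  f30 <- fit_lognormal_mixture(gen_fluorescence(specs$tg30nM))
  expect_true(f30$converged)
  expect_false(f30$degenerate)
  expect_lte(f30$nonresponder$mu, f30$responder$mu)  # label convention
  expect_lt(abs(f30$alpha - 0.38), 0.02)
  expect_lt(abs(f30$responder$mu - 3.61), 0.05)
  expect_lt(abs(f30$nonresponder$mu - 2.37), 0.05)
  expect_true(all(diff(f30$em_trajectory) >= -1e-9))  # monotone EM

  fhk <- fit_lognormal_mixture(gen_fluorescence(specs$highK))
  expect_lt(abs(fhk$alpha - 0.31), 0.02)
  expect_lt(abs(fhk$responder$mu - 4.07), 0.05)
})

test_that("EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))  # Mclust needs its namespace attached
  spec <- lognormal_population_spec(list(c(weight = 0.4, mu = 2.3, sigma = 0.2),
                                         c(weight = 0.6, mu = 3.5, sigma = 0.6)),
                                    3000, seed = 44)
  v <- gen_fluorescence(spec)
  ours <- fit_lognormal_mixture(v)
  mc <- mclust::Mclust(log10(v), G = 2, modelNames = "V", verbose = FALSE)
  expect_lt(abs(ours$loglik - mc$loglik), 1)  # same data (log10 values), same optimum
  ord <- order(mc$parameters$mean)
  expect_lt(abs(ours$alpha - mc$parameters$pro[ord[1]]), 0.01)
  expect_lt(abs(ours$nonresponder$mu - mc$parameters$mean[ord[1]]), 0.01)
  expect_lt(abs(ours$responder$mu - mc$parameters$mean[ord[2]]), 0.01)
})

test_that("single-component data drive the mixture to a flagged boundary", {
  spec <- lognormal_population_spec(list(c(weight = 1, mu = 2.1, sigma = 0.2)),
                                    500, seed = 45)
  f <- fit_lognormal_mixture(gen_fluorescence(spec))
  expect_true(f$degenerate || min(f$alpha, 1 - f$alpha) < 0.05 ||
                abs(f$responder$mu - f$nonresponder$mu) < 0.1)
})

test_that("mixture recovery is stable across replicates", {
  # 50 replicates at N = 15000 from the low-dose parameter set
  alphas <- vapply(1:50, function(s) {
    spec <- lognormal_population_spec(
      list(c(weight = 0.38, mu = 2.37, sigma = 0.17),
           c(weight = 0.62, mu = 3.61, sigma = 0.75)), 15000, seed = 1000 + s)
    fit_lognormal_mixture(gen_fluorescence(spec))$alpha
  }, numeric(1))
  expect_lt(abs(mean(alphas) - 0.38), 0.02)
})

test_that("mixture median solves the half-mass equation", {
  one <- fit_lognormal(c(10, 1000))  # mu = 2
  expect_equal(mixture_median(one), 100)

  spec <- facs_reference_specs(seed = 46)$tg30nM
  fit <- fit_lognormal_mixture(gen_fluorescence(spec))
  med <- mixture_median(fit)
  oracle <- scan_mixture_median(c(fit$alpha, 1 - fit$alpha),
                                c(fit$nonresponder$mu, fit$responder$mu),
                                c(fit$nonresponder$sigma, fit$responder$sigma))
  expect_lt(abs(med - oracle) / oracle, 1e-4)  # oracle limited by its grid
  expect_equal(fraction_above(fit, med), 0.5)
})

test_that("closed-form mixture mean matches Monte Carlo and exceeds median", {
  deg <- fit_lognormal(c(100, 100, 100))
  expect_equal(mixture_mean(deg), 100)

  spec <- lognormal_population_spec(list(c(weight = 1, mu = 2, sigma = 0.21)),
                                    1e6, seed = 47)
  v <- gen_fluorescence(spec)
  cf <- mixture_mean(fit_lognormal(v))
  expect_lt(abs(cf - mean(v)) / mean(v), 3 * sd(v) / mean(v) / sqrt(1e6))

  mixfit <- fit_lognormal_mixture(gen_fluorescence(facs_reference_specs(seed = 48)$tg30nM))
  expect_gt(mixture_mean(mixfit), mixture_median(mixfit))  # log-normal skew
})

test_that("fraction_above follows the >= convention in both modes", {
  v <- c(10, 100, 1000)
  expect_equal(fraction_above(v, 5), 1)
  expect_equal(fraction_above(v, 100), 2 / 3)   # inclusive at the threshold
  expect_error(fraction_above(v, -1), "threshold")

  fit <- fit_lognormal(c(10, 1000))
  expect_equal(fraction_above(fit, 100), 0.5)
  # model-mode tail checked against a Monte-Carlo oracle
  spec <- facs_reference_specs(seed = 49)$tg30nM
  vals <- gen_fluorescence(spec)
  fit2 <- fit_lognormal_mixture(vals)
  p_model <- fraction_above(fit2, 1000)
  p_emp <- mean(vals >= 1000)
  expect_lt(abs(p_model - p_emp), 3 * sqrt(p_emp * (1 - p_emp) / length(vals)) + 0.01)
  # monotone non-increasing in the threshold
  ths <- 10^seq(1, 5, length.out = 40)
  expect_true(all(diff(vapply(ths, fraction_above, numeric(1), x = fit2)) <= 0))
})

test_that("blank-derived threshold doubles the blank maximum", {
  expect_equal(derive_blank_threshold(c(100, 250, 500)), 1000)
  expect_equal(derive_blank_threshold(1), 2)
  expect_equal(derive_blank_threshold(c(5, 10, 1e4)), 2e4)  # max, not quantile
  expect_error(derive_blank_threshold(numeric(0)), "empty")
})

test_that("quadrant statistics match direct counting and sum to 100", {
  q <- quadrant_stats(c(1, 1, 1), c(1, 2, 3), 10, 10)
  expect_equal(q$q4, 100)
  q4 <- quadrant_stats(c(1, 20, 20, 1), c(20, 20, 1, 1), 10, 10)
  expect_equal(c(q4$q1, q4$q2, q4$q3, q4$q4), rep(25, 4))

  set.seed(50)
  x <- 10^rnorm(1e4, 2.5, 0.6); y <- 10^rnorm(1e4, 2.5, 0.6)
  q <- quadrant_stats(x, y, 300, 400)
  expect_equal(q$q2, 100 * sum(x > 300 & y > 400) / 1e4)
  expect_equal(q$q1 + q$q2 + q$q3 + q$q4, 100)
  expect_error(quadrant_stats(1:3, 1:4, 1, 1), "equal length")
})

test_that("reporter positivity clears autofluorescence by 3 SDs", {
  blank <- c(80, 100, 120)  # mean 100, sd 20 -> threshold 160
  res <- reporter_positive(c(161, 160, 100), blank)
  expect_equal(res$threshold, 160)
  expect_identical(res$positive, c(TRUE, FALSE, FALSE))  # strict inequality
  expect_error(reporter_positive(100, blank_values = 5), "at least 2")

  # values drawn from the blank distribution: ~0.13% clear the 3-SD bar
  set.seed(51)
  blank_big <- rnorm(2e5, 100, 20)
  res2 <- reporter_positive(rnorm(2e5, 100, 20), blank_big)
  expect_lt(abs(res2$fraction - pnorm(-3)), 5e-4)
})
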