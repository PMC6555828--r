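# Nuclear-proportion transform and binomial activating-unit fits.

test_that("nuclear proportion transform is correct and bijective", {
  expect_equal(to_nuclear_proportion(c(0, 1, 3)), c(0, 0.5, 0.75))
  expect_error(to_nuclear_proportion(-0.1), "ratio")
  expect_error(to_nuclear_proportion(Inf), "ratio")
  # bijection [0, inf) -> [0, 1): inverse is p/(1-p)
  r <- c(0, 10^seq(-6, 6, length.out = 50))
  p <- to_nuclear_proportion(r)
  expect_true(all(p >= 0 & p < 1))
  expect_true(all(diff(p) > 0))
  # roundtrip is exact to float conditioning: tight for moderate ratios,
  # relative ~(1 + r) * eps as p approaches 1
  mod <- r <= 10
  expect_lt(max(abs(p[mod] / (1 - p[mod]) - r[mod])), 1e-12)
  expect_lt(max(abs(p / (1 - p) - r) / pmax(r, 1)), 1e-9)
})

test_that("translocation records derive ratio and proportion consistently", {
  rec <- translocation_records(c("c1", "c2"), "tg", nuclear = c(50, 150),
                               cytosolic = c(100, 50))
  expect_equal(rec$ratio, c(0.5, 3))
  expect_equal(rec$proportion, c(1 / 3, 0.75))
  expect_lt(max(abs(rec$proportion - rec$ratio / (1 + rec$ratio))), 1e-12)
  expect_error(translocation_records("c", "x", nuclear = 1, cytosolic = 0),
               "cytosolic")
})

test_that("single binomial fit equals the closed-form MLE", {
  expect_equal(fit_binomial(c(0.5, 0.5, 0.5), 10)$components$p, 0.5)
  expect_equal(fit_binomial(c(0.2, 0.4, 0.6), 10)$components$p, 0.4)
  expect_error(fit_binomial(numeric(0), 10), "cells")

  spec <- binomial_population_spec(13, list(c(weight = 1, p = 0.7)), 500,
                                   seed = 21)
  x <- gen_nuclear_proportions(spec)
  fit <- fit_binomial(x, 13)
  expect_lt(abs(fit$components$p - 0.7), 3 * sqrt(0.7 * 0.3 / (500 * 13)))
  # cross-check the closed form against an independent likelihood grid
  k <- round(13 * x)
  expect_lt(abs(fit$components$p - grid_binom_p(k, 13)), 1e-4)
})

test_that("half-integer proportions discretize half-up", {
  # 0.25 * 2 units = 0.5 -> k = 1 (round half-up), so p-hat = 0.5 not 0
  expect_equal(fit_binomial(c(0.25, 0.25), 2)$components$p, 0.5)
})

test_that("profile_n recovers the generating unit count on lattice data", {
  spec <- binomial_population_spec(8, list(c(weight = 1, p = 0.5)), 2000,
                                   seed = 42)
  x <- gen_nuclear_proportions(spec)
  pr <- profile_n(list(ctl = x), 1:30)
  expect_equal(pr$n_units, 8)

  # identical data in two conditions: same n, identical p-hats
  pr2 <- profile_n(list(a = x, b = x), 1:30)
  expect_equal(pr2$n_units, 8)
  expect_equal(pr2$fits$a$components$p, pr2$fits$b$components$p)

  # all-zero data: every n ties, tie-break picks the smallest grid value
  pr0 <- profile_n(list(a = rep(0, 100)), 2:30)
  expect_equal(pr0$n_units, 2)
  expect_equal(pr0$fits$a$components$p, 0)
})

test_that("binomial mixture EM recovers a responder/non-responder split", {
  spec <- binomial_population_spec(13, list(c(weight = 0.2, p = 0.1),
                                            c(weight = 0.8, p = 0.85)),
                                   2000, seed = 7)
  x <- gen_nuclear_proportions(spec)
  fit <- fit_binomial_mixture(x, 13)
  expect_true(fit$converged)
  expect_false(fit$degenerate)
  # label convention: non-responder has the smaller p
  expect_lt(fit$components$p[1], fit$components$p[2])
  expect_lt(abs(fit$components$weight[1] - 0.2), 3 * sqrt(0.2 * 0.8 / 2000))
  # EM log-likelihood is monotone non-decreasing
  expect_true(all(diff(fit$em_trajectory) >= -1e-9))
})

test_that("EM solution matches the exhaustive grid-search oracle", {
  spec <- binomial_population_spec(8, list(c(weight = 0.3, p = 0.15),
                                           c(weight = 0.7, p = 0.8)),
                                   80, seed = 33)
  x <- gen_nuclear_proportions(spec)
  fit <- fit_binomial_mixture(x, 8)
  oracle <- grid_binom_mixture(round(8 * x), 8, step = 0.01)
  expect_gte(fit$loglik, oracle$loglik - 1e-6)
  expect_lt(abs(fit$components$weight[1] - oracle$w), 0.0100001)
  expect_lt(abs(fit$components$p[1] - oracle$p1), 0.0100001)
  expect_lt(abs(fit$components$p[2] - oracle$p2), 0.0100001)
})

test_that("single-population data yield a degenerate mixture fit", {
  spec <- binomial_population_spec(13, list(c(weight = 1, p = 0.8)), 300,
                                   seed = 9)
  fit <- fit_binomial_mixture(gen_nuclear_proportions(spec), 13)
  # either a vanishing component or two collapsed p's
  expect_true(fit$degenerate ||
                abs(diff(fit$components$p)) < 0.05 ||
                min(fit$components$weight) < 0.02)
})

test_that("modality classification separates unimodal from bimodal", {
  uni <- binomial_population_spec(13, list(c(weight = 1, p = 0.8)), 1000,
                                  seed = 14)
  expect_equal(classify_modality(gen_nuclear_proportions(uni), 13)$classification,
               "unimodal")
  bi <- binomial_population_spec(13, list(c(weight = 0.4, p = 0.05),
                                          c(weight = 0.6, p = 0.9)),
                                 1000, seed = 15)
  res <- classify_modality(gen_nuclear_proportions(bi), 13)
  expect_equal(res$classification, "bimodal")
  expect_gt(res$delta_bic, 0)
  expect_error(classify_modality(c(0.1, 0.2, 0.3, 0.4, 0.5), 13), "20 cells")
})

test_that("parametric bootstrap LRT calibrates against unimodal data", {
  uni <- binomial_population_spec(13, list(c(weight = 1, p = 0.6)), 300,
                                  seed = 16)
  res <- classify_modality(gen_nuclear_proportions(uni), 13,
                           bootstrap_B = 49, seed = 17)
  expect_gt(res$p_value, 0.05)
  bi <- binomial_population_spec(13, list(c(weight = 0.4, p = 0.05),
                                          c(weight = 0.6, p = 0.9)),
                                 300, seed = 18)
  res2 <- classify_modality(gen_nuclear_proportions(bi), 13,
                            bootstrap_B = 49, seed = 17)
  expect_lte(res2$p_value, 0.05)
})

test_that("responder posteriors behave like Bayes probabilities", {
  spec <- binomial_population_spec(13, list(c(weight = 0.2, p = 0.05),
                                            c(weight = 0.8, p = 0.9)),
                                   2000, seed = 19)
  x <- gen_nuclear_proportions(spec)
  fit <- fit_binomial_mixture(x, 13)
  post <- responder_posteriors(fit, x)
  expect_true(all(post >= 0 & post <= 1))
  # EM stationarity: mean posterior equals the fitted responder weight
  expect_lt(abs(mean(post) - fit$components$weight[2]), 1e-6)
  # a cell at proportion 0 under widely separated components is a non-responder
  expect_lt(responder_posteriors(fit, 0), 1e-6)

  one <- fit_binomial(x, 13)
  expect_error(responder_posteriors(one, x), "two-component")
})

test_that("equal components give all-0.5 posteriors", {
  fit <- fit_binomial_mixture(runif(50), 10)
  fit$components$weight <- c(0.5, 0.5)
  fit$components$p <- c(0.4, 0.4)
  expect_equal(responder_posteriors(fit, c(0, 0.3, 1)), rep(0.5, 3))
})
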