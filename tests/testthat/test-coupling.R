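test_that("poisson_cdf agrees with brute-force pmf summation and handles edge cases", {
  set.seed(3)
  lams <- c(0, 0.5, 1, 5, 20, 33, 60, 100)
  ks <- c(-1, 0, 1, 5, 27, 50, 120, 200)
  for (lam in lams) {
    for (k in ks) {
      expect_equal(poisson_cdf(k, lam), brute_poisson_cdf(k, lam),
                   tolerance = 1e-12,
                   label = sprintf("poisson_cdf(%d, %g)", k, lam))
    }
  }
  expect_equal(poisson_cdf(0, 1), exp(-1), tolerance = 1e-12)
  expect_equal(poisson_cdf(-1, 5), 0)
  expect_equal(poisson_cdf(7, 0), 1)
  expect_error(poisson_cdf(2, -1), "non-negative")
  expect_error(poisson_cdf(2.5, 1), "integer")
})

test_that("predict_te matches the hand-computed model values", {
  params <- coupling_params()
  # plateau: CDF term < 1e-4 at d = 45
  expect_lt(abs(predict_te(45, "W", params) - 0.9), 1e-4)
  # oracle evaluation at d = 18 (lambda = 33)
  expect_equal(predict_te(18, "W", params),
               0.9 * (1 - brute_poisson_cdf(27, 33)), tolerance = 1e-12)
  # te0 = 0 kills the curve
  p0 <- coupling_params(te0 = 0)
  expect_equal(predict_te(c(0, 10, 50), "W", p0), c(0, 0, 0))
})

test_that("predict_te curve is monotone, bounded by te0, and decreasing in the offset", {
  set.seed(42)
  for (i in 1:5) {
    params <- coupling_params(te0 = runif(1, 0.3, 1),
                              alpha = sample(5:50, 1),
                              offsets = c(W = sample(0:30, 1)))
    te <- predict_te(0:100, "W", params)
    expect_true(all(diff(te) >= -1e-12))
    expect_true(all(te >= 0 & te <= params$te0 + 1e-12))
    expect_lt(params$te0 - predict_te(400, "W", params), 1e-9)
  }
  # a larger offset c means more distal ribosome mass, hence higher TE at
  # equal d — the W-over-R ordering in the measured curves is driven by c
  lo <- coupling_params(offsets = c(S = 5))
  hi <- coupling_params(offsets = c(S = 20))
  expect_true(all(predict_te(0:40, "S", hi) >= predict_te(0:40, "S", lo)))
  expect_gt(predict_te(15, "S", hi), predict_te(15, "S", lo))
  w_r <- coupling_params()
  expect_true(all(predict_te(9:30, "W", w_r) > predict_te(9:30, "R", w_r)))
})

test_that("predict_te rejects unknown series and negative Poisson means", {
  params <- coupling_params(offsets = c(W = -8))
  expect_error(predict_te(10, "Q", params), "unknown series")
  expect_error(predict_te(5, "W", params), "non-negative")
})

test_that("the strict CDF convention shifts the threshold by one mass point", {
  inc <- coupling_params(cdf_convention = "inclusive")
  str <- coupling_params(cdf_convention = "strict")
  d <- 0:60
  expect_true(all(predict_te(d, "W", str) >= predict_te(d, "W", inc)))
  expect_equal(predict_te(10, "W", str) - predict_te(10, "W", inc),
               0.9 * (brute_poisson_cdf(27, 25) - brute_poisson_cdf(26, 25)),
               tolerance = 1e-12)
})

test_that("grid fit exactly recovers generating parameters on noiseless data", {
  params <- coupling_params()
  tab <- make_te_table(params, distances = list(W = 5:48), sigma = 0,
                       replicates = 1, seed = 1)
  fit <- fit_coupling(tab)
  expect_equal(fit$params$alpha, 27L)
  expect_equal(fit$params$te0, 0.9, tolerance = 1e-9)
  expect_equal(unname(fit$params$offsets["W"]), 15L)
  expect_lt(fit$rss, 1e-12)
})

test_that("joint two-series noiseless fit recovers both offsets exactly", {
  params <- coupling_params()
  tab <- make_te_table(params, distances = list(W = 5:48, R = 9:59),
                       sigma = 0, replicates = 1, seed = 2)
  fit <- fit_coupling(tab)
  expect_equal(fit$params$alpha, 27L)
  expect_equal(unname(fit$params$offsets[c("W", "R")]), c(15L, 7L))
  expect_lt(fit$rss, 1e-12)
})

test_that("grid fit recovers parameters from noisy replicated data", {
  params <- coupling_params()
  tab <- make_te_table(params, sigma = 0.02, replicates = 3, seed = 5)
  fit <- fit_coupling(tab)
  expect_lte(abs(fit$params$alpha - 27L), 1L)
  expect_lt(abs(fit$params$te0 - 0.9), 0.02)
  expect_lte(abs(fit$params$offsets[["W"]] - 15L), 1L)
  expect_lte(abs(fit$params$offsets[["R"]] - 7L), 1L)
})

test_that("fit validates its inputs and reports degeneracy", {
  expect_error(fit_coupling(tibble::tibble()), "must contain columns")
  params <- coupling_params()
  tab <- make_te_table(params, distances = list(W = c(5, 10, 15)),
                       sigma = 0, replicates = 1)
  expect_error(fit_coupling(tab), ">= 4 points")
  # a grid on which every predicted mass is zero is unidentifiable
  tab2 <- make_te_table(params, distances = list(W = 10:14), sigma = 0,
                        replicates = 1)
  expect_error(fit_coupling(tab2, alpha_range = 60, c_range = -10),
               "unidentifiable")
  tab4 <- make_te_table(params, distances = list(W = c(5, 10, 15, 20, 25)),
                        sigma = 0, replicates = 1)
  expect_error(
    fit_coupling(dplyr::mutate(tab4, te_se = 0), weights = "inverse_se2"),
    "te_se"
  )
})

test_that("inverse-variance weights favour precise points", {
  params <- coupling_params()
  tab <- make_te_table(params, distances = list(W = 5:48), sigma = 0,
                       replicates = 1)
  tab$te_se <- 0.01
  # corrupt one point but give it a huge SE: the weighted fit ignores it
  tab$te[10] <- tab$te[10] + 0.5
  tab$te_se[10] <- 100
  fit_w <- fit_coupling(tab, weights = "inverse_se2")
  expect_equal(fit_w$params$alpha, 27L)
  expect_equal(fit_w$params$te0, 0.9, tolerance = 1e-3)
})

test_that("bootstrap intervals collapse on exact data and behave on noisy data", {
  params <- coupling_params()
  tab <- make_te_table(params, distances = list(W = 5:48), sigma = 0,
                       replicates = 1)
  fit <- fit_coupling(tab, alpha_range = 20:35, c_range = 5:25)
  fit_b <- suppressWarnings(bootstrap_ci(fit, B = 100, seed = 4))
  ci <- fit_b$bootstrap
  expect_lt(max(ci$conf.high - ci$conf.low), 1e-9)
  expect_equal(unname(ci$conf.low[ci$term == "te0"]), 0.9, tolerance = 1e-9)

  tabn <- make_te_table(params, distances = list(W = 5:48), sigma = 0.02,
                        replicates = 3, seed = 8)
  fitn <- fit_coupling(tabn, alpha_range = 20:35, c_range = 5:25)
  fitn <- bootstrap_ci(fitn, B = 120, seed = 9)
  ci_te0 <- fitn$bootstrap[fitn$bootstrap$term == "te0", ]
  expect_lte(ci_te0$conf.low, 0.9)
  expect_gte(ci_te0$conf.high, 0.9)

  expect_error(bootstrap_ci(fit, B = 0), "positive")
  expect_warning(bootstrap_ci(fit, B = 50, seed = 1), "unstable")
})

test_that("tidy, glance and the objective grid expose the fit consistently", {
  params <- coupling_params()
  tab <- make_te_table(params, distances = list(W = 5:48), sigma = 0,
                       replicates = 1)
  fit <- fit_coupling(tab, alpha_range = 25:29, c_range = 13:17,
                      keep_grid = TRUE)
  td <- tidy(fit)
  expect_setequal(td$term, c("te0", "alpha", "c_W"))
  gl <- glance(fit)
  expect_equal(gl$n_points, nrow(tab))
  # the reported optimum really is the grid minimum
  expect_equal(min(fit$objective_grid$rss), fit$rss)
  best <- fit$objective_grid[which.min(fit$objective_grid$rss), ]
  expect_equal(best$alpha, fit$params$alpha)
  expect_s3_class(autoplot(fit), "ggplot")
})
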