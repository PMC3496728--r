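zt7 <- seq(2, 26, by = 4)

test_that("cosine_predict peaks at the acrophase and troughs 12 h later", {
  expect_equal(cosine_predict(18, mesor = 2, amplitude = 1.5, acrophase = 18),
               3.5)
  expect_equal(cosine_predict(6, mesor = 2, amplitude = 1.5, acrophase = 18),
               0.5)
  expect_equal(cosine_predict(0:23, mesor = 2, amplitude = 0, acrophase = 5),
               rep(2, 24))
})

test_that("least-squares fit recovers a noiseless cosine exactly", {
  y <- cosine_predict(zt7, mesor = 0, amplitude = 1, acrophase = 18)
  fit <- cosinor_ls(zt7, y)
  expect_equal(fit$mesor, 0, tolerance = 1e-10)
  expect_equal(fit$amplitude, 1, tolerance = 1e-10)
  expect_equal(fit$acrophase, 18, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$amplitude_pt, 2 * fit$amplitude)
  expect_equal(fit$peak_zt_grid, 18)
})

test_that("least-squares coefficients match an lm() normal-equations oracle", {
  set.seed(91)
  for (i in 1:5) {
    y <- cosine_predict(zt7, 0.3, 0.8, 7) + rnorm(7, sd = 0.4)
    fit <- cosinor_ls(zt7, y)
    w <- 2 * pi / 24
    oracle <- lm(y ~ cos(w * zt7) + sin(w * zt7))
    bc <- coef(oracle)[2]; bs <- coef(oracle)[3]
    expect_equal(fit$mesor, unname(coef(oracle)[1]), tolerance = 1e-8)
    expect_equal(fit$amplitude, unname(sqrt(bc^2 + bs^2)), tolerance = 1e-8)
    expect_equal(fit$acrophase,
                 unname((atan2(bs, bc) * 24 / (2 * pi)) %% 24),
                 tolerance = 1e-8)
    expect_equal(fit$r2, summary(oracle)$r.squared, tolerance = 1e-8)
    expect_equal(fit$r2_adj, summary(oracle)$adj.r.squared, tolerance = 1e-8)
  }
})

test_that("degenerate series are handled: constant y, short y, bad grid", {
  expect_warning(fit <- cosinor_ls(zt7, rep(2, 7)), "constant")
  expect_equal(fit$amplitude, 0)
  expect_equal(fit$r2, 0)
  expect_true(is.na(fit$acrophase))
  expect_error(cosinor_ls(c(0, 6, 12), c(1, 2, 3)), "at least 4")
  expect_error(cosinor_ls(c(0, 24, 48, 72), rnorm(4)), "distinct")
})

test_that("adjusted R2 reproduces the published R2 -> adjusted pairs", {
  # n = 7 timepoints, k = 2 trigonometric regressors
  expect_equal(adjusted_r2(0.86, 7), 0.79, tolerance = 0.005)
  expect_equal(adjusted_r2(0.66, 7), 0.49, tolerance = 0.005)
  expect_equal(adjusted_r2(0.46, 7), 0.19, tolerance = 0.005)
  expect_equal(adjusted_r2(1, 7), 1)
  expect_equal(adjusted_r2(1, 12, 3), 1)
  expect_error(adjusted_r2(0.5, 3), "n > k")
  # negative when r2 < k/(n-1), matching the published 0.19 -> -0.2 row
  expect_equal(adjusted_r2(0.19, 7), -0.215, tolerance = 1e-9)
  expect_lt(adjusted_r2(0.19, 7), 0)
})

test_that("Monte-Carlo search is seed-deterministic and converges on ls", {
  y <- cosine_predict(zt7, mesor = 0.2, amplitude = 1, acrophase = 18)
  a <- cosinor_mc(zt7, y, n_sims = 2e4, top_k = 100, seed = 42)
  b <- cosinor_mc(zt7, y, n_sims = 2e4, top_k = 100, seed = 42)
  expect_identical(a[setdiff(names(a), c("zt", "y"))],
                   b[setdiff(names(b), c("zt", "y"))])

  ls <- cosinor_ls(zt7, y)
  mc <- cosinor_mc(zt7, y, n_sims = 1e5, top_k = 400, seed = 7)
  expect_lt(abs(mc$amplitude - ls$amplitude), 0.05)
  expect_lt(abs(mc$r2 - ls$r2), 0.02)
  expect_lt(min(abs(mc$acrophase - ls$acrophase),
                24 - abs(mc$acrophase - ls$acrophase)), 0.5)
  expect_error(cosinor_mc(zt7, y, n_sims = 10, top_k = 100), "n_sims >= top_k")
})

test_that("Monte-Carlo error against the ls oracle shrinks with n_sims", {
  err <- sapply(c(1e3, 1e4, 1e5), function(ns) {
    mean(sapply(1:10, function(s) {
      y <- cosine_predict(zt7, 0, 1, 18) +
        withr::with_seed(s, rnorm(7, sd = 0.2))
      ls <- cosinor_ls(zt7, y)
      mc <- cosinor_mc(zt7, y, n_sims = ns, top_k = min(ns / 10, 400),
                       seed = s)
      abs(mc$r2 - ls$r2)
    }))
  })
  expect_true(all(diff(err) < 0))
})

test_that("permutation p-value is seeded, small for a perfect fit, and tied
           to the observed R2", {
  grid <- c(0, 3, 7, 11, 14, 19, 22)
  y <- cosine_predict(grid, 0, 1, 18)
  fit <- cosinor_ls(grid, y)
  p1 <- cosinor_pvalue(grid, y, fit$r2, n_perm = 999, seed = 4)
  p2 <- cosinor_pvalue(grid, y, fit$r2, n_perm = 999, seed = 4)
  expect_identical(p1, p2)
  # observed R2 = 1: only shuffles reproducing the series itself can tie
  expect_lte(p1, 5 / 1000)
  expect_gte(p1, 1 / 1000)
  # a lower claimed R2 can only raise the count of as-good permutations
  expect_gte(cosinor_pvalue(grid, y, 0.2, n_perm = 999, seed = 4), p1)
})

test_that("amplitude and phase recovery at study geometry holds on average", {
  res <- purrr::map_dfr(1:200, function(s) {
    y <- cosine_predict(zt7, 0, 1, 18) +
      withr::with_seed(s, rnorm(7, sd = 0.5))
    fit <- cosinor_ls(zt7, y)
    dphi <- abs(fit$acrophase - 18)
    tibble::tibble(da = fit$amplitude - 1, dphi = min(dphi, 24 - dphi))
  })
  expect_lt(abs(mean(res$da)), 0.15)
  expect_lt(mean(res$dphi), 1.5)
})

test_that("peak time maps the acrophase to the nearest sampled hour", {
  y <- cosine_predict(zt7, 0, 1, 18)
  fit <- cosinor_ls(zt7, y)
  expect_equal(peak_zt(fit),
               tibble::tibble(peak_zt_continuous = 18, peak_zt_grid = 18))

  # off-grid acrophase: circular distances 1.9 (to 6) vs 2.1 (to 10)
  y2 <- cosine_predict(zt7, 0, 1, 7.9)
  fit2 <- cosinor_ls(zt7, y2)
  pk <- peak_zt(fit2)
  expect_equal(pk$peak_zt_continuous, 7.9, tolerance = 1e-9)
  expect_equal(pk$peak_zt_grid, 6)

  # exact tie between two grid hours resolves to the earlier one
  expect_equal(antclock:::peak_on_grid(4, c(2, 6, 10)), 2)

  expect_warning(flat <- cosinor_ls(zt7, rep(1, 7)))
  expect_true(all(is.na(peak_zt(flat))))
})

test_that("fit_rhythms tidies per-gene fits with order-independent seeds", {
  ct <- simulate_qpcr(sim_config(seed = 21))
  agg <- aggregate_colonies(quantify_expression(ct, "EF1a"))
  fits <- fit_rhythms(agg, method = "ls", n_perm = 99, seed = 5)
  expect_equal(nrow(fits), 8)
  expect_true(all(fits$r2_adj <= fits$r2))
  expect_equal(fits$amplitude_pt, 2 * fits$amplitude)
  shuffled <- fit_rhythms(agg[sample(nrow(agg)), ], method = "ls",
                          n_perm = 99, seed = 5)
  expect_equal(fits, shuffled)
})
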