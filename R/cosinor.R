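#' Evaluate a fixed-period cosine model
#'
#' The single-component cosinor curve y(t) = M + A cos(2 pi (t - phi) /
#' period): M is the mesor (rhythm-adjusted mean), A the amplitude (half the
#' peak-to-trough extent) and phi the acrophase (hour of peak).
#'
#' @param t Time in hours (vector).
#' @param mesor,amplitude,acrophase Cosinor parameters.
#' @param period Period in hours; 24 for a circadian fit.
#' @return Predicted values, same length as `t`.
#' @export
cosine_predict <- function(t, mesor, amplitude, acrophase, period = 24) {
  mesor + amplitude * cos(2 * pi * (t - acrophase) / period)
}

# design matrix {1, cos(wt), sin(wt)} for the linearized cosinor
cosinor_design <- function(zt, period) {
  w <- 2 * pi / period
  cbind(1, cos(w * zt), sin(w * zt))
}

check_cosinor_series <- function(zt, y, period) {
  if (length(zt) != length(y)) abort("zt and y must have equal length")
  if (length(y) < 4) abort("cosinor fit needs at least 4 timepoints")
  if (!all(is.finite(zt)) || !all(is.finite(y))) abort("zt and y must be finite")
  if (length(unique(round(zt %% period, 9))) < 3) {
    abort("cosinor fit needs at least 3 distinct timepoints modulo the period")
  }
}

new_cosinor_fit <- function(mesor, amplitude, acrophase, period, r2, r2_adj,
                            p_value, method, zt, y,
                            n_sims = NA_integer_, top_k = NA_integer_,
                            seed = NA_integer_) {
  grid <- peak_on_grid(acrophase, zt, period)
  structure(
    list(
      mesor = mesor, amplitude = amplitude,
      acrophase = acrophase, period = period,
      r2 = r2, r2_adj = r2_adj,
      amplitude_pt = 2 * amplitude,
      peak_zt_continuous = if (amplitude > 0) acrophase %% period else NA_real_,
      peak_zt_grid = if (amplitude > 0) grid else NA_real_,
      p_value = p_value, method = method,
      n_sims = n_sims, top_k = top_k, seed = seed,
      n = length(y), zt = zt, y = y
    ),
    class = "cosinor_fit"
  )
}

# nearest sampled zt (mod period) to the acrophase; ties go to the earlier zt
peak_on_grid <- function(acrophase, zts, period = 24) {
  if (is.na(acrophase)) return(NA_real_)
  grid <- sort(unique(zts %% period))
  d <- abs(grid - (acrophase %% period))
  d <- pmin(d, period - d)
  grid[which.min(d)] # which.min takes the first (earliest) minimum
}

#' Closed-form least-squares cosinor fit
#'
#' Fits y(t) = M + A cos(2 pi (t - phi) / period) with the period held fixed
#' by ordinary least squares on the linearized regressors
#' {1, cos(wt), sin(wt)}: A = sqrt(bc^2 + bs^2) and
#' phi = atan2(bs, bc) * period / (2 pi). This is the exact optimum that the
#' Monte-Carlo search [cosinor_mc()] approximates.
#'
#' A constant series has no variance to explain; it returns A = 0, R2 = 0
#' and an undefined acrophase, with a warning.
#'
#' @param zt Sampling times in hours.
#' @param y Expression values (typically z-scores).
#' @param period Fixed period in hours (default 24).
#' @return A `cosinor_fit` object; see [tidy.cosinor_fit()] and
#'   [glance.cosinor_fit()].
#' @examples
#' zt <- seq(2, 26, by = 4)
#' y <- cosine_predict(zt, mesor = 0, amplitude = 1, acrophase = 18)
#' cosinor_ls(zt, y)
#' @export
cosinor_ls <- function(zt, y, period = 24) {
  check_cosinor_series(zt, y, period)
  n <- length(y)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    warn("constant series: cosinor amplitude set to 0, R2 to 0")
    return(new_cosinor_fit(
      mesor = y[1], amplitude = 0, acrophase = NA_real_, period = period,
      r2 = 0, r2_adj = adjusted_r2(0, n, 2), p_value = NA_real_,
      method = "ls", zt = zt, y = y
    ))
  }
  X <- cosinor_design(zt, period)
  qrx <- qr(X)
  if (qrx$rank < 3) abort("collinear cosinor design (degenerate zt grid)")
  beta <- qr.coef(qrx, y)
  sse <- sum((y - X %*% beta)^2)
  r2 <- 1 - sse / sst
  amplitude <- sqrt(beta[2]^2 + beta[3]^2)
  acrophase <- (atan2(beta[3], beta[2]) * period / (2 * pi)) %% period
  new_cosinor_fit(
    mesor = unname(beta[1]), amplitude = unname(amplitude),
    acrophase = unname(acrophase), period = period,
    r2 = r2, r2_adj = adjusted_r2(r2, n, 2), p_value = NA_real_,
    method = "ls", zt = zt, y = y
  )
}

#' Monte-Carlo random-search cosinor fit
#'
#' Draws `n_sims` parameter triples (M, A, phi) uniformly from `ranges`,
#' scores each candidate curve by its R2 against the series, and averages
#' the `top_k` best: arithmetic means for mesor and amplitude, a circular
#' mean for the acrophase. Deterministic given `seed`. As `n_sims` grows
#' the result converges on the closed-form optimum of [cosinor_ls()].
#'
#' Two ways of reporting R2 are supported. The default (`"refit"`)
#' evaluates the R2 of the curve built from the averaged parameters, which
#' is unbiased around the optimum and converges quickly. `"mean"` instead
#' averages the top-k candidate R2 values themselves; because the best
#' 0.4 percent of a three-dimensional uniform box still spans a sizeable
#' neighbourhood of the optimum, this estimate sits noticeably below the
#' least-squares R2 unless `n_sims` is very large (at 1e7 draws the two
#' agree to a few thousandths).
#'
#' @inheritParams cosinor_ls
#' @param n_sims Number of random candidate parameter sets.
#' @param top_k Number of best-scoring candidates averaged.
#' @param seed Integer seed controlling the random draws.
#' @param ranges Optional named list with elements `mesor`, `amplitude`,
#'   `acrophase`, each a length-2 numeric range. Defaults to the data-driven
#'   box M in [min(y), max(y)], A in [0, max(y) - min(y)], phi in [0, period).
#' @param r2_aggregation How the reported R2 is formed from the top-k
#'   candidates: `"refit"` (default, R2 of the averaged-parameter curve) or
#'   `"mean"` (arithmetic mean of the candidate R2 values).
#' @return A `cosinor_fit` object with `method = "mc"`.
#' @export
cosinor_mc <- function(zt, y, n_sims = 1e5, top_k = 400, seed = 1,
                       period = 24, ranges = NULL,
                       r2_aggregation = c("refit", "mean")) {
  r2_aggregation <- match.arg(r2_aggregation)
  check_cosinor_series(zt, y, period)
  if (top_k < 1 || n_sims < top_k) abort("need n_sims >= top_k >= 1")
  if (is.null(ranges)) {
    ranges <- list(
      mesor = range(y),
      amplitude = c(0, diff(range(y))),
      acrophase = c(0, period)
    )
  }
  n <- length(y)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    warn("constant series: cosinor amplitude set to 0, R2 to 0")
    return(new_cosinor_fit(
      mesor = y[1], amplitude = 0, acrophase = NA_real_, period = period,
      r2 = 0, r2_adj = adjusted_r2(0, n, 2), p_value = NA_real_,
      method = "mc", zt = zt, y = y,
      n_sims = as.integer(n_sims), top_k = as.integer(top_k),
      seed = as.integer(seed)
    ))
  }
  w <- 2 * pi / period
  draws <- withr::with_seed(seed, list(
    mesor = runif(n_sims, ranges$mesor[1], ranges$mesor[2]),
    amplitude = runif(n_sims, ranges$amplitude[1], ranges$amplitude[2]),
    acrophase = runif(n_sims, ranges$acrophase[1], ranges$acrophase[2])
  ))
  # pred[i, j] = M_i + A_i * cos(w * (zt_j - phi_i)), expanded so the whole
  # candidate population is scored with three outer products
  ct <- cos(w * zt); st <- sin(w * zt)
  cp <- cos(w * draws$acrophase); sp <- sin(w * draws$acrophase)
  pred <- draws$mesor +
    (draws$amplitude * cp) %o% ct + (draws$amplitude * sp) %o% st
  sse <- rowSums((pred - rep(y, each = n_sims))^2)
  r2_all <- 1 - sse / sst
  top <- order(r2_all, decreasing = TRUE)[seq_len(top_k)]
  phi_top <- draws$acrophase[top]
  phi_bar <- (atan2(mean(sin(w * phi_top)), mean(cos(w * phi_top))) / w) %% period
  m_bar <- mean(draws$mesor[top])
  a_bar <- mean(draws$amplitude[top])
  r2 <- switch(r2_aggregation,
    refit = 1 - sum((y - cosine_predict(zt, m_bar, a_bar, phi_bar,
                                        period))^2) / sst,
    mean = mean(r2_all[top])
  )
  new_cosinor_fit(
    mesor = m_bar,
    amplitude = a_bar,
    acrophase = phi_bar, period = period,
    r2 = r2,
    r2_adj = adjusted_r2(r2, n, 2),
    p_value = NA_real_, method = "mc", zt = zt, y = y,
    n_sims = as.integer(n_sims), top_k = as.integer(top_k),
    seed = as.integer(seed)
  )
}

#' Adjusted R-squared
#'
#' 1 - (1 - R2)(n - 1)/(n - k - 1), penalizing the coefficient of
#' determination for the k regressors. For the fixed-period cosinor k = 2
#' (the cosine and sine terms); with few timepoints the adjustment is large
#' and can be negative for poor fits.
#'
#' @param r2 Unadjusted R-squared.
#' @param n Number of observations.
#' @param k Number of regressors excluding the intercept (default 2).
#' @return Adjusted R-squared (may be negative).
#' @examples
#' adjusted_r2(0.86, n = 7) # 0.79
#' @export
adjusted_r2 <- function(r2, n, k = 2) {
  if (any(n <= k + 1)) abort("adjusted_r2() needs n > k + 1")
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

#' Permutation p-value for a cosinor fit
#'
#' Shuffles the series over its own timepoints `n_perm` times, refits the
#' least-squares cosinor to each shuffle, and reports
#' p = (1 + #{permuted R2 >= observed R2}) / (n_perm + 1). This tests the
#' null that expression carries no time-of-day structure while conditioning
#' on the observed values. Deterministic given `seed`.
#'
#' @inheritParams cosinor_ls
#' @param observed_r2 The R2 whose significance is tested (from
#'   [cosinor_ls()] or [cosinor_mc()]).
#' @param n_perm Number of random permutations.
#' @param seed Integer seed for the shuffles.
#' @return A p-value in (0, 1].
#' @export
cosinor_pvalue <- function(zt, y, observed_r2, n_perm = 999, seed = 1,
                           period = 24) {
  check_cosinor_series(zt, y, period)
  if (n_perm < 1) abort("n_perm must be >= 1")
  n <- length(y)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(1)
  X <- cosinor_design(zt, period)
  proj <- X %*% solve(crossprod(X), t(X)) # hat matrix; grid is fixed
  perms <- withr::with_seed(seed, {
    matrix(replicate(n_perm, sample.int(n)), nrow = n)
  })
  Y <- matrix(y[perms], nrow = n)
  sse <- colSums((Y - proj %*% Y)^2)
  r2_perm <- 1 - sse / sst
  (1 + sum(r2_perm >= observed_r2 - 1e-12)) / (n_perm + 1)
}

#' Peak time of a fitted cosinor
#'
#' The continuous peak is the acrophase reduced modulo the period; the grid
#' peak is the sampled zt (mod period) nearest to it in circular distance,
#' ties resolved toward the earlier hour. A flat fit (amplitude 0) has no
#' peak and returns missing values.
#'
#' @param fit A `cosinor_fit`.
#' @param zts Sampled timepoints; defaults to the ones the fit was made on.
#' @return A tibble with columns `peak_zt_continuous` and `peak_zt_grid`.
#' @export
peak_zt <- function(fit, zts = fit$zt) {
  stopifnot(inherits(fit, "cosinor_fit"))
  if (fit$amplitude == 0 || is.na(fit$acrophase)) {
    return(tibble(peak_zt_continuous = NA_real_, peak_zt_grid = NA_real_))
  }
  tibble(
    peak_zt_continuous = fit$acrophase %% fit$period,
    peak_zt_grid = peak_on_grid(fit$acrophase, zts, fit$period)
  )
}

#' Fit cosinor rhythms to every gene in a tidy expression table
#'
#' Maps [cosinor_mc()] or [cosinor_ls()] over genes (and colonies, when a
#' `colony` column is present) and attaches a permutation p-value for each
#' fit. The value column is `mean_z` for cross-colony aggregates from
#' [aggregate_colonies()], otherwise `zscore`. Each series gets its own
#' deterministic sub-seed derived from `seed` and the series' rank in the
#' sorted group order, so results do not depend on row order.
#'
#' @param data Tibble with `gene`, `zt` and a value column (`mean_z` or
#'   `zscore`); an optional `colony` column switches to per-colony fits.
#' @param method `"mc"` (Monte-Carlo search, default) or `"ls"`
#'   (closed-form).
#' @inheritParams cosinor_mc
#' @param n_perm Permutations for the p-value; 0 skips the test.
#' @return One row per fitted series: `gene` (and `colony`), `mesor`,
#'   `amplitude`, `acrophase`, `peak_zt`, `peak_zt_grid`, `r2`, `r2_adj`,
#'   `amplitude_pt`, `p_value`, `method`, `n_sims`, `top_k`, `seed`.
#' @export
fit_rhythms <- function(data, method = c("mc", "ls"), n_sims = 1e5,
                        top_k = 400, n_perm = 999, seed = 1, period = 24) {
  method <- match.arg(method)
  value_col <- if ("mean_z" %in% names(data)) "mean_z" else "zscore"
  if (!all(c("gene", "zt", value_col) %in% names(data))) {
    abort("fit_rhythms() needs columns gene, zt and mean_z or zscore")
  }
  keys <- intersect(c("gene", "colony"), names(data))
  groups <- data |>
    arrange(across(all_of(c(keys, "zt")))) |>
    group_by(across(all_of(keys))) |>
    group_split()
  purrr::list_rbind(purrr::imap(groups, function(g, i) {
    sub_seed <- (seed + 1009L * i) %% .Machine$integer.max
    zt <- g$zt
    y <- g[[value_col]]
    fit <- switch(method,
      mc = cosinor_mc(zt, y, n_sims = n_sims, top_k = top_k,
                      seed = sub_seed, period = period),
      ls = cosinor_ls(zt, y, period = period)
    )
    p <- if (n_perm > 0) {
      cosinor_pvalue(zt, y, fit$r2, n_perm = n_perm, seed = sub_seed,
                     period = period)
    } else {
      NA_real_
    }
    bind_cols(
      g[1, keys, drop = FALSE],
      tibble(
        mesor = fit$mesor, amplitude = fit$amplitude,
        acrophase = fit$acrophase,
        peak_zt = fit$peak_zt_continuous, peak_zt_grid = fit$peak_zt_grid,
        r2 = fit$r2, r2_adj = fit$r2_adj, amplitude_pt = fit$amplitude_pt,
        p_value = p, method = method,
        n_sims = if (method == "mc") as.integer(n_sims) else NA_integer_,
        top_k = if (method == "mc") as.integer(top_k) else NA_integer_,
        seed = as.integer(sub_seed)
      )
    )
  }))
}
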