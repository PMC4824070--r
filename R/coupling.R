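#' Parameters of the ribosome-RNAP coupling model
#'
#' Container for the parameters of the stochastic coupling model
#' \deqn{TE(d) = TE_0 \, [1 - CDF(\alpha, \lambda(d))], \qquad \lambda(d) = d + c,}
#' where \eqn{d} is the spacer length (nt) between the last base of the
#' upstream stop codon and the first nt of the terminator hairpin stem,
#' \eqn{\alpha} is the occlusion threshold (the pioneer ribosome represses
#' hairpin folding only when its distance to the hairpin at RNAP arrival is
#' at most \eqn{\alpha} nt), \eqn{TE_0} is the maximal (unrepressed)
#' termination efficiency, and CDF is the Poisson cumulative distribution of
#' the ribosome-hairpin distance with mean \eqn{d + c}; the offset \eqn{c} is
#' series specific (sequence-specific coupling dynamics).
#'
#' Defaults are the fitted values for the lambda-phage tR2 terminator:
#' `te0 = 0.9`, `alpha = 27` nt, `c = 15` nt for the W series and `c = 7` nt
#' for the R series.
#'
#' @param te0 Maximal termination efficiency, in \eqn{[0, 1]}.
#' @param alpha Occlusion threshold in nt, non-negative integer.
#' @param offsets Named numeric vector of per-series lambda offsets `c`
#'   (nt, integers), e.g. `c(W = 15, R = 7)`.
#' @param cdf_convention Whether repression occurs when the ribosome-hairpin
#'   distance X satisfies `X <= alpha` (`"inclusive"`, the default) or
#'   `X <= alpha - 1` (`"strict"`). The two conventions differ by one Poisson
#'   mass point; see the package vignette.
#'
#' @return An object of class `coupling_params`.
#' @seealso [predict_te()], [fit_coupling()]
#' @export
#' @examples
#' params <- coupling_params()
#' predict_te(c(5, 18, 45), "W", params)
coupling_params <- function(te0 = 0.9, alpha = 27, offsets = c(W = 15, R = 7),
                            cdf_convention = c("inclusive", "strict")) {
  cdf_convention <- match.arg(cdf_convention)
  if (!is.numeric(te0) || length(te0) != 1 || is.na(te0) || te0 < 0 || te0 > 1) {
    abort("`te0` must be a single value in [0, 1].")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha < 0 || alpha != round(alpha)) {
    abort("`alpha` must be a single non-negative integer (nt).")
  }
  if (length(offsets) < 1 || is.null(names(offsets)) || any(!nzchar(names(offsets)))) {
    abort("`offsets` must be a named vector of per-series lambda offsets.")
  }
  if (any(is.na(offsets)) || any(offsets != round(offsets))) {
    abort("`offsets` must be integers (nt).")
  }
  structure(
    list(
      te0 = as.numeric(te0),
      alpha = as.integer(alpha),
      offsets = stats::setNames(as.integer(offsets), names(offsets)),
      cdf_convention = cdf_convention
    ),
    class = "coupling_params"
  )
}

#' @export
print.coupling_params <- function(x, ...) {
  cat("Ribosome-RNAP coupling model parameters\n")
  cat(sprintf("  TE0   : %.3f\n", x$te0))
  cat(sprintf("  alpha : %d nt (%s convention)\n", x$alpha, x$cdf_convention))
  cat(sprintf("  lambda(d) = d + c with c: %s\n",
              paste(sprintf("%s = %d", names(x$offsets), x$offsets),
                    collapse = ", ")))
  invisible(x)
}

# K such that repression <=> X <= K
.repression_k <- function(alpha, cdf_convention) {
  if (identical(cdf_convention, "strict")) alpha - 1L else as.integer(alpha)
}

#' Poisson cumulative distribution function
#'
#' \eqn{P[X \le k]} for \eqn{X \sim Poisson(\lambda)}, evaluated through the
#' regularized incomplete gamma function (via [stats::ppois()]). `k = -1`
#' returns 0; any `k >= 0` with `lambda = 0` returns 1. Vectorized over both
#' arguments.
#'
#' @param k Integer quantile(s), each `>= -1`.
#' @param lambda Poisson mean(s), each `>= 0`.
#' @return Probabilities in \eqn{[0, 1]}.
#' @export
#' @examples
#' poisson_cdf(0, 1)    # exp(-1)
#' poisson_cdf(-1, 5)   # 0
poisson_cdf <- function(k, lambda) {
  if (any(is.na(k)) || any(k != round(k)) || any(k < -1)) {
    abort("`k` must be integer(s) >= -1.")
  }
  if (any(is.na(lambda)) || any(lambda < 0)) {
    abort("`lambda` must be non-negative.")
  }
  ppois(k, lambda)
}

#' Predict termination efficiency from the coupling model
#'
#' Evaluates \eqn{TE(d) = TE_0 [1 - CDF(K, d + c)]} where `K` is `alpha`
#' (inclusive convention) or `alpha - 1` (strict), and `c` is the offset for
#' the requested series.
#'
#' @param d Stop-codon-to-hairpin distance(s) in nt, non-negative integers.
#' @param series Series label(s) present in `params$offsets` (recycled).
#' @param params A [coupling_params()] object.
#' @return Numeric vector of predicted TEs.
#' @export
predict_te <- function(d, series, params = coupling_params()) {
  stopifnot(inherits(params, "coupling_params"))
  if (any(is.na(d)) || any(d < 0) || any(d != round(d))) {
    abort("`d` must be non-negative integer distance(s) in nt.")
  }
  series <- as.character(series)
  unknown <- setdiff(unique(series), names(params$offsets))
  if (length(unknown) > 0) {
    abort(sprintf("unknown series: %s (offsets defined for %s)",
                  paste(unknown, collapse = ", "),
                  paste(names(params$offsets), collapse = ", ")))
  }
  lam <- d + as.numeric(params$offsets[series])
  if (any(lam < 0)) {
    abort("d + c < 0 for some inputs; the Poisson mean must be non-negative.")
  }
  k <- .repression_k(params$alpha, params$cdf_convention)
  params$te0 * (1 - poisson_cdf(k, lam))
}

#' Tabulate the model TE-distance curve
#'
#' @param params A [coupling_params()] object.
#' @param d Integer distances at which to evaluate the curve.
#' @param series Series to evaluate; defaults to all series in `params`.
#' @return A tibble with columns `series`, `distance_nt`, `te_pred`.
#' @export
predicted_curve <- function(params = coupling_params(), d = 0:100,
                            series = names(params$offsets)) {
  tidyr::expand_grid(series = series, distance_nt = as.integer(d)) |>
    dplyr::mutate(te_pred = predict_te(.data$distance_nt, .data$series, params))
}

# Per-series sufficient statistics for the closed-form TE0 profile:
# for each (alpha, c) grid point, s1 = sum w*te*m and s2 = sum w*m^2 with
# m_i = 1 - CDF(K, d_i + c). Grid rows with any d + c < 0 are invalid (NA).
.series_grid_stats <- function(d, te, w, alpha_range, c_range, cdf_convention) {
  lam <- outer(c_range, d, "+")                  # n_c x n_pts
  invalid <- rowSums(lam < 0) > 0
  lam[lam < 0] <- 0                               # placeholder; masked below
  n_a <- length(alpha_range)
  s1 <- matrix(NA_real_, n_a, length(c_range))
  s2 <- matrix(NA_real_, n_a, length(c_range))
  for (i in seq_len(n_a)) {
    k <- .repression_k(alpha_range[i], cdf_convention)
    m <- 1 - ppois(k, lam)
    s1[i, ] <- as.numeric(m %*% (w * te))
    s2[i, ] <- as.numeric((m * m) %*% w)
  }
  s1[, invalid] <- NA_real_
  s2[, invalid] <- NA_real_
  list(s1 = s1, s2 = s2)
}

#' Fit the coupling model to a TE-distance table
#'
#' Exhaustive-grid least squares for the coupling model: the occlusion
#' threshold `alpha` (shared across series) and the per-series lambda offsets
#' `c` are searched over integer grids; at each grid point the maximal TE
#' `te0` (shared across series) has the closed-form conditional
#' least-squares solution
#' \deqn{\hat{TE}_0 = \sum_i w_i te_i m_i / \sum_i w_i m_i^2, \qquad
#'       m_i = 1 - CDF(K, d_i + c_{s(i)}),}
#' clamped to \eqn{[0, 1]}. The global minimizer of the (optionally weighted)
#' residual sum of squares is returned; ties are broken by the smallest
#' `alpha`, then the smallest offsets in series order.
#'
#' @param data Data frame with columns `series`, `distance_nt`, `te`
#'   (one row per measurement; replicates are separate rows), and `te_se`
#'   when `weights = "inverse_se2"`.
#' @param alpha_range,c_range Integer grids searched for `alpha` and for the
#'   per-series offsets. Defaults bracket all footprint-plausible geometries.
#' @param weights `"none"` (unweighted, default) or `"inverse_se2"`
#'   (weights \eqn{1/se^2} from `te_se`).
#' @param cdf_convention See [coupling_params()].
#' @param keep_grid If `TRUE`, attach the full `(alpha, c)` objective grid
#'   (one tibble row per grid point) to the result as `$objective_grid`.
#' @return An object of class `te_fit`: a list with elements `params`
#'   ([coupling_params()]), `rss`, `n_points`, `data`, and optionally
#'   `objective_grid` and (after [bootstrap_ci()]) `bootstrap`.
#' @seealso [tidy.te_fit()], [glance.te_fit()], [autoplot.te_fit()]
#' @export
fit_coupling <- function(data, alpha_range = 0:60, c_range = -10:40,
                         weights = c("none", "inverse_se2"),
                         cdf_convention = c("inclusive", "strict"),
                         keep_grid = FALSE) {
  weights <- match.arg(weights)
  cdf_convention <- match.arg(cdf_convention)
  req <- c("series", "distance_nt", "te")
  if (!is.data.frame(data) || !all(req %in% names(data))) {
    abort("`data` must contain columns series, distance_nt, te.")
  }
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) abort("`data` is empty.")
  if (any(is.na(data$te)) || any(is.na(data$distance_nt))) {
    abort("`te` and `distance_nt` must not contain missing values.")
  }
  if (any(data$distance_nt < 0) || any(data$distance_nt != round(data$distance_nt))) {
    abort("`distance_nt` must be non-negative integers.")
  }
  alpha_range <- sort(unique(as.integer(alpha_range)))
  c_range <- sort(unique(as.integer(c_range)))
  if (any(alpha_range < 0)) abort("`alpha_range` must be non-negative.")

  series_levels <- unique(as.character(data$series))
  counts <- table(as.character(data$series))
  if (any(counts < 4)) {
    abort(sprintf("need >= 4 points per series; series %s has %d",
                  names(counts)[which.min(counts)], min(counts)))
  }
  w <- if (weights == "inverse_se2") {
    if (!"te_se" %in% names(data) || any(is.na(data$te_se)) || any(data$te_se <= 0)) {
      abort("weights = \"inverse_se2\" requires positive `te_se` for every row.")
    }
    1 / data$te_se^2
  } else {
    rep(1, nrow(data))
  }

  stats_by_series <- lapply(series_levels, function(s) {
    idx <- as.character(data$series) == s
    .series_grid_stats(data$distance_nt[idx], data$te[idx], w[idx],
                       alpha_range, c_range, cdf_convention)
  })
  names(stats_by_series) <- series_levels
  sum_wte2 <- sum(w * data$te^2)

  n_s <- length(series_levels)
  best <- list(rss = Inf, alpha = NA_integer_, c_idx = NULL, te0 = NA_real_)
  grid_rows <- if (keep_grid) vector("list", length(alpha_range)) else NULL
  any_identifiable <- FALSE

  for (i in seq_along(alpha_range)) {
    # accumulate S1, S2 over the cartesian product of per-series offsets
    S1 <- stats_by_series[[1]]$s1[i, ]
    S2 <- stats_by_series[[1]]$s2[i, ]
    if (n_s > 1) {
      for (j in 2:n_s) {
        S1 <- outer(S1, stats_by_series[[j]]$s1[i, ], "+")
        S2 <- outer(S2, stats_by_series[[j]]$s2[i, ], "+")
      }
    }
    te0 <- pmin(1, pmax(0, S1 / S2))
    rss <- sum_wte2 - 2 * te0 * S1 + te0^2 * S2
    rss[is.na(rss)] <- Inf
    rss[S2 <= 0] <- Inf                           # model degenerate (all m = 0)
    if (any(is.finite(rss))) any_identifiable <- TRUE
    jmin <- which.min(rss)                        # column-major: first series' c fastest
    if (rss[jmin] < best$rss) {
      best$rss <- rss[jmin]
      best$alpha <- alpha_range[i]
      best$c_idx <- arrayInd(jmin, .dim = rep(length(c_range), n_s))[1, ]
      best$te0 <- te0[jmin]
    }
    if (keep_grid) {
      idx_all <- arrayInd(seq_along(rss), .dim = rep(length(c_range), n_s))
      row <- tibble::tibble(alpha = alpha_range[i], rss = as.numeric(rss),
                            te0 = as.numeric(te0))
      for (j in seq_len(n_s)) {
        row[[paste0("c_", series_levels[j])]] <- c_range[idx_all[, j]]
      }
      grid_rows[[i]] <- row
    }
  }

  if (!any_identifiable || !is.finite(best$rss)) {
    abort("unidentifiable: the model is degenerate on this data (all m = 0 on the searched grid).")
  }

  offsets <- stats::setNames(c_range[best$c_idx], series_levels)
  fit <- structure(
    list(
      params = coupling_params(best$te0, best$alpha, offsets, cdf_convention),
      rss = best$rss,
      n_points = nrow(data),
      data = data,
      weights = weights,
      alpha_range = alpha_range,
      c_range = c_range
    ),
    class = "te_fit"
  )
  if (keep_grid) fit$objective_grid <- dplyr::bind_rows(grid_rows)
  fit
}

#' @export
print.te_fit <- function(x, ...) {
  cat("Coupling-model fit (exhaustive integer grid, least squares)\n")
  print(x$params)
  cat(sprintf("  rss = %.6g on %d points (%s weights)\n",
              x$rss, x$n_points, x$weights))
  if (!is.null(x$bootstrap)) {
    cat(sprintf("  bootstrap: B = %d (%d degenerate resamples skipped)\n",
                attr(x$bootstrap, "B"), attr(x$bootstrap, "n_skipped")))
  }
  invisible(x)
}

#' Case-resampling bootstrap intervals for a coupling-model fit
#'
#' Resamples constructs (unique `construct_id` when present, otherwise unique
#' `(series, distance_nt)` pairs) with replacement within each series, refits
#' the full grid search on each resample, and returns percentile 95%
#' intervals for `te0`, `alpha`, and each offset. Resamples on which the fit
#' is degenerate are skipped and counted.
#'
#' @param fit A `te_fit` from [fit_coupling()].
#' @param B Number of bootstrap resamples (>= 100; smaller values error at 0
#'   and warn below 100).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return The `te_fit` with a `bootstrap` tibble attached (columns `term`,
#'   `conf.low`, `conf.high`), invisibly carrying attributes `B`, `n_skipped`
#'   and the resampled estimates in `attr(, "estimates")`.
#' @export
bootstrap_ci <- function(fit, B = 500, seed = 1) {
  stopifnot(inherits(fit, "te_fit"))
  if (B <= 0) abort("`B` must be positive.")
  if (B < 100) warn("B < 100 gives unstable percentile intervals.")
  data <- fit$data
  unit_key <- if ("construct_id" %in% names(data)) {
    as.character(data$construct_id)
  } else {
    paste(data$series, data$distance_nt, sep = "@")
  }
  units <- split(seq_len(nrow(data)), unit_key)
  unit_series <- vapply(units, function(ix) as.character(data$series[ix[1]]), "")
  by_series <- split(names(units), unit_series)

  set.seed(seed)
  ests <- vector("list", B)
  n_skipped <- 0L
  for (b in seq_len(B)) {
    take <- unlist(lapply(by_series, function(u) {
      sample(u, length(u), replace = TRUE)
    }), use.names = FALSE)
    rows <- unlist(units[take], use.names = FALSE)
    res <- tryCatch(
      fit_coupling(data[rows, , drop = FALSE],
                   alpha_range = fit$alpha_range, c_range = fit$c_range,
                   weights = fit$weights,
                   cdf_convention = fit$params$cdf_convention),
      error = function(e) NULL
    )
    if (is.null(res)) {
      n_skipped <- n_skipped + 1L
      next
    }
    ests[[b]] <- c(te0 = res$params$te0, alpha = res$params$alpha,
                   stats::setNames(as.numeric(res$params$offsets),
                                   paste0("c_", names(res$params$offsets))))
  }
  est <- do.call(rbind, ests[!vapply(ests, is.null, TRUE)])
  if (is.null(est) || nrow(est) == 0) {
    abort("all bootstrap resamples were degenerate.")
  }
  ci <- tibble::tibble(
    term = colnames(est),
    conf.low = apply(est, 2, quantile, probs = 0.025, names = FALSE),
    conf.high = apply(est, 2, quantile, probs = 0.975, names = FALSE)
  )
  attr(ci, "B") <- B
  attr(ci, "n_skipped") <- n_skipped
  attr(ci, "estimates") <- est
  fit$bootstrap <- ci
  fit
}

#' Tidy a coupling-model fit
#'
#' @param x A `te_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`te0`, `alpha`, one offset
#'   per series), with percentile bootstrap intervals when present.
#' @method tidy te_fit
#' @export
tidy.te_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = c("te0", "alpha", paste0("c_", names(x$params$offsets))),
    estimate = c(x$params$te0, x$params$alpha, as.numeric(x$params$offsets))
  )
  if (!is.null(x$bootstrap)) {
    out <- dplyr::left_join(out, x$bootstrap, by = "term")
  }
  out
}

#' One-row summary of a coupling-model fit
#'
#' @param x A `te_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `te0`, `alpha`, `rss`, `n_points`,
#'   `cdf_convention`.
#' @method glance te_fit
#' @export
glance.te_fit <- function(x, ...) {
  tibble::tibble(
    te0 = x$params$te0,
    alpha = x$params$alpha,
    rss = x$rss,
    n_points = x$n_points,
    cdf_convention = x$params$cdf_convention
  )
}

#' Plot a coupling-model fit
#'
#' Measured TEs (points, with +/- 1 SE bars when `te_se` is present) overlaid
#' with the fitted model curve per series.
#'
#' @param object A `te_fit` object.
#' @param d_range Integer distances over which to draw the fitted curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot te_fit
#' @export
autoplot.te_fit <- function(object, d_range = NULL, ...) {
  data <- object$data
  if (is.null(d_range)) {
    d_range <- seq(min(data$distance_nt), max(data$distance_nt))
  }
  curve <- predicted_curve(object$params, d = d_range,
                           series = unique(as.character(data$series)))
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$distance_nt, y = .data$te,
                                          colour = .data$series)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(y = .data$te_pred, colour = .data$series)) +
    ggplot2::labs(x = "stop codon to hairpin distance d (nt)",
                  y = "termination efficiency",
                  colour = "series") +
    ggplot2::theme_minimal()
  if ("te_se" %in% names(data) && !all(is.na(data$te_se))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$te - .data$te_se, ymax = .data$te + .data$te_se),
      width = 0.5
    )
  }
  p
}
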