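#' Select the exponential-growth window of a growth curve
#'
#' Picks the longest contiguous run of time points whose OD lies in
#' `[od_min, od_max]`, then trims end points (whichever end most improves the
#' log-linear fit) until the R-squared of ln(OD) vs time reaches `r2_min` or
#' only three points remain.
#'
#' @param series Data frame with columns `time_min` and `od600`.
#' @param od_min,od_max OD600 bounds of the exponential window.
#' @param r2_min Minimal R-squared of the ln(OD) regression on the window.
#' @return Integer vector of row indices into `series`.
#' @export
select_exponential_window <- function(series, od_min = 0.02, od_max = 0.3,
                                      r2_min = 0.99) {
  stopifnot(is.data.frame(series), all(c("time_min", "od600") %in% names(series)))
  od <- series$od600
  t <- series$time_min
  in_range <- od >= od_min & od <= od_max
  if (!any(in_range)) abort("no points fall inside the OD window.")
  runs <- rle(in_range)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  best_run <- keep[which.max(runs$lengths[keep])]
  idx <- seq(starts[best_run], ends[best_run])
  if (length(idx) < 3) abort("insufficient points: the OD window holds fewer than 3 points.")
  r2_of <- function(ix) {
    if (length(unique(t[ix])) < 2) return(0)
    y <- log(od[ix])
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(0)
    1 - sum(lm(y ~ t[ix])$residuals^2) / tss
  }
  while (length(idx) > 3 && r2_of(idx) < r2_min) {
    drop_head <- idx[-1]
    drop_tail <- idx[-length(idx)]
    idx <- if (r2_of(drop_head) >= r2_of(drop_tail)) drop_head else drop_tail
  }
  if (r2_of(idx) < r2_min) {
    warn(sprintf("exponential window R^2 = %.4f is below %.2f", r2_of(idx), r2_min))
  }
  idx
}

#' Estimate the exponential growth rate
#'
#' Least-squares slope of ln(OD600) vs time (minutes) on a window of points.
#' A constant OD yields `mu = 0` with `r2 = 0` and a warning (the regression
#' R-squared is undefined there).
#'
#' @param series Data frame with columns `time_min` and `od600`.
#' @param window Integer row indices; defaults to all rows.
#' @return A one-row tibble with `mu` (per minute), `r2` and `n_points`.
#' @export
estimate_growth_rate <- function(series, window = seq_len(nrow(series))) {
  stopifnot(is.data.frame(series), all(c("time_min", "od600") %in% names(series)))
  if (length(window) < 3) abort("insufficient points: need >= 3 points in the window.")
  od <- series$od600[window]
  t <- series$time_min[window]
  if (any(is.na(od)) || any(od <= 0)) abort("invalid OD: OD600 must be positive on the window.")
  y <- log(od)
  if (isTRUE(all.equal(var(y), 0))) {
    warn("constant OD on the window; growth rate reported as 0.")
    return(tibble::tibble(mu = 0, r2 = 0, n_points = length(window)))
  }
  fit <- lm(y ~ t)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  tibble::tibble(mu = unname(coef(fit)[2]), r2 = r2, n_points = length(window))
}

#' Estimate the fluorescence-per-OD slope f
#'
#' The promoter-activity slope \eqn{f = \partial F / \partial OD}: the OLS
#' slope of background-subtracted fluorescence against OD600 over the window.
#'
#' @param series Data frame with `od600` and the fluorescence column for
#'   `channel` (`f_rfp` or `f_gfp`).
#' @param channel `"rfp"` or `"gfp"`.
#' @param window Integer row indices; defaults to all rows.
#' @param background Constant background fluorescence subtracted from F.
#' @return The slope (fluorescence units per OD600 unit).
#' @export
estimate_f_slope <- function(series, channel = c("gfp", "rfp"),
                             window = seq_len(nrow(series)), background = 0) {
  channel <- match.arg(channel)
  col <- paste0("f_", channel)
  stopifnot(is.data.frame(series), all(c("od600", col) %in% names(series)))
  if (length(window) < 3) abort("insufficient points: need >= 3 points in the window.")
  od <- series$od600[window]
  f <- series[[col]][window] - background
  if (isTRUE(all.equal(var(od), 0))) abort("degenerate window: OD has zero variance.")
  unname(coef(lm(f ~ od))[2])
}

#' Per-cell protein synthesis rate with maturation correction
#'
#' \eqn{P = \mu f (1 + \mu\tau/\ln 2)}: the apparent fluorescence
#' accumulation rate per cell, corrected for the maturation half-time
#' \eqn{\tau} of the fluorophore (immature protein is invisible; under
#' balanced exponential growth the correction factor is \eqn{1 + \mu\tau/\ln 2}).
#'
#' @param mu Growth rate per minute, positive.
#' @param f_slope Fluorescence-per-OD slope from [estimate_f_slope()].
#' @param tau Maturation half-time in minutes, non-negative.
#' @return Synthesis rate in fluorescence units per OD per minute.
#' @export
synthesis_rate <- function(mu, f_slope, tau) {
  if (any(tau < 0)) abort("`tau` must be non-negative.")
  if (any(mu <= 0)) abort("`mu` must be positive.")
  mu * f_slope * (1 + mu * tau / log(2))
}

#' Termination efficiency from dual-reporter synthesis rates
#'
#' \eqn{TE = 1 - (P_{GFP}/P_{GFP,ref}) / (P_{RFP}/P_{RFP,ref})}: the
#' downstream (GFP) synthesis rate relative to the terminator-free reference,
#' normalized by the upstream (RFP) rate ratio to cancel promoter and
#' copy-number variation. Not clipped: small negative values can occur under
#' noise and are preserved for fitting.
#'
#' @param p_gfp,p_rfp Synthesis rates of the construct.
#' @param p_gfp_ref,p_rfp_ref Synthesis rates of the terminator-free
#'   reference construct.
#' @return Termination efficiency (dimensionless, <= 1).
#' @export
te_dual <- function(p_gfp, p_rfp, p_gfp_ref, p_rfp_ref) {
  if (any(p_gfp_ref <= 0) || any(p_rfp_ref <= 0) || any(p_rfp <= 0)) {
    abort("invalid normalization: reference rates and p_rfp must be positive.")
  }
  1 - (p_gfp / p_gfp_ref) / (p_rfp / p_rfp_ref)
}

#' Termination efficiency from the GFP channel only
#'
#' \eqn{TE = 1 - P_{GFP}/P_{GFP,ref}}, used when the upstream RFP gene is
#' modified (its fluorescence no longer comparable to the reference) and the
#' upstream mRNA level is independently known to be unchanged.
#'
#' @param p_gfp Construct GFP synthesis rate.
#' @param p_gfp_ref Reference GFP synthesis rate, positive.
#' @return Termination efficiency (may be negative under readthrough
#'   exceeding the reference; flagged with a warning, not clipped).
#' @export
te_gfp_only <- function(p_gfp, p_gfp_ref) {
  if (any(p_gfp_ref <= 0)) abort("invalid normalization: p_gfp_ref must be positive.")
  te <- 1 - p_gfp / p_gfp_ref
  if (any(te < 0)) warn("negative TE: GFP expression exceeds the reference.")
  te
}

# Per-replicate synthesis rates for one construct's measurements.
.replicate_rates <- function(meas, tau_gfp, tau_rfp, background,
                             od_min, od_max, r2_min) {
  meas |>
    dplyr::group_by(.data$replicate) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$time_min)
      win <- select_exponential_window(df, od_min = od_min, od_max = od_max,
                                       r2_min = r2_min)
      gr <- estimate_growth_rate(df, win)
      f_g <- estimate_f_slope(df, "gfp", win, background = background[["gfp"]])
      f_r <- estimate_f_slope(df, "rfp", win, background = background[["rfp"]])
      tibble::tibble(
        mu = gr$mu, r2 = gr$r2,
        p_gfp = synthesis_rate(gr$mu, f_g, tau_gfp),
        p_rfp = synthesis_rate(gr$mu, f_r, tau_rfp)
      )
    }) |>
    dplyr::ungroup()
}

#' Quantify one construct's termination efficiency
#'
#' Runs the full chain for a single construct: exponential-window selection,
#' growth rate, fluorescence-per-OD slopes, maturation-corrected synthesis
#' rates per channel, then the dual-reporter TE (or GFP-only TE when
#' `rfp_modified`). TE is computed per replicate against the mean reference
#' synthesis rates, then aggregated as mean and standard error.
#'
#' @param measurements Long data frame for one construct: columns
#'   `replicate`, `time_min`, `od600`, `f_rfp`, `f_gfp`.
#' @param reference_measurements Same-shaped data frame for the
#'   terminator-free reference construct.
#' @param rfp_modified If `TRUE`, use [te_gfp_only()] instead of [te_dual()].
#' @param tau_gfp,tau_rfp Maturation half-times in minutes.
#' @param background Named numeric `c(rfp = , gfp = )` background fluorescence.
#' @param od_min,od_max,r2_min Exponential-window parameters,
#'   see [select_exponential_window()].
#' @return A one-row tibble: `te`, `te_se`, `method`, `n_replicates`, `mu`.
#' @export
quantify_construct <- function(measurements, reference_measurements,
                               rfp_modified = FALSE,
                               tau_gfp = 15, tau_rfp = 40,
                               background = c(rfp = 0, gfp = 0),
                               od_min = 0.02, od_max = 0.3, r2_min = 0.99) {
  if (any(c(tau_gfp, tau_rfp) < 0)) abort("`tau` must be non-negative.")
  ref <- .replicate_rates(tibble::as_tibble(reference_measurements),
                          tau_gfp, tau_rfp, background, od_min, od_max, r2_min)
  con <- .replicate_rates(tibble::as_tibble(measurements),
                          tau_gfp, tau_rfp, background, od_min, od_max, r2_min)
  p_gfp_ref <- mean(ref$p_gfp)
  p_rfp_ref <- mean(ref$p_rfp)
  te_rep <- if (rfp_modified) {
    te_gfp_only(con$p_gfp, p_gfp_ref)
  } else {
    te_dual(con$p_gfp, con$p_rfp, p_gfp_ref, p_rfp_ref)
  }
  n <- length(te_rep)
  tibble::tibble(
    te = mean(te_rep),
    te_se = if (n > 1) sd(te_rep) / sqrt(n) else 0,
    method = if (rfp_modified) "gfp_only" else "dual",
    n_replicates = n,
    mu = mean(con$mu)
  )
}

#' Quantify termination efficiencies for a panel of constructs
#'
#' Maps [quantify_construct()] over a construct table, pairing every
#' construct with the panel's reference (the row with `is_reference = TRUE`).
#'
#' @param measurements Long data frame: `construct_id`, `replicate`,
#'   `time_min`, `od600`, `f_rfp`, `f_gfp`.
#' @param constructs Construct table: `construct_id`, `series`,
#'   `distance_nt`, `rfp_modified`, `is_reference` (and any further columns,
#'   carried through).
#' @inheritParams quantify_construct
#' @return A TE table tibble: `construct_id`, `series`, `distance_nt`, `te`,
#'   `te_se`, `method`, `n_replicates` (plus `translation_coupled` when the
#'   construct table carries it — uncoupled constructs do not follow the
#'   coupling model and should be excluded before [fit_coupling()]).
#' @export
#' @examples
#' params <- coupling_params()
#' panel <- make_construct_panel(params)
#' meas <- make_growth_series(panel, noise = noise_model(0, 0, replicates = 1))
#' quantify_te(meas, panel)
quantify_te <- function(measurements, constructs,
                        tau_gfp = 15, tau_rfp = 40,
                        background = c(rfp = 0, gfp = 0),
                        od_min = 0.02, od_max = 0.3, r2_min = 0.99) {
  measurements <- tibble::as_tibble(measurements)
  constructs <- tibble::as_tibble(constructs)
  if (sum(constructs$is_reference) != 1) {
    abort("`constructs` must contain exactly one reference (is_reference = TRUE).")
  }
  ref_id <- constructs$construct_id[constructs$is_reference]
  ref_meas <- dplyr::filter(measurements, .data$construct_id == ref_id)
  if (nrow(ref_meas) == 0) abort("no measurements found for the reference construct.")
  constructs |>
    dplyr::filter(!.data$is_reference) |>
    dplyr::rowwise() |>
    dplyr::group_map(function(row, key) {
      meas <- dplyr::filter(measurements, .data$construct_id == row$construct_id)
      if (nrow(meas) == 0) {
        abort(sprintf("no measurements for construct %s", row$construct_id))
      }
      res <- quantify_construct(
        meas, ref_meas,
        rfp_modified = isTRUE(row$rfp_modified),
        tau_gfp = tau_gfp, tau_rfp = tau_rfp, background = background,
        od_min = od_min, od_max = od_max, r2_min = r2_min
      )
      out <- dplyr::bind_cols(
        tibble::tibble(construct_id = row$construct_id, series = row$series,
                       distance_nt = row$distance_nt),
        dplyr::select(res, "te", "te_se", "method", "n_replicates")
      )
      if ("translation_coupled" %in% names(row)) {
        out$translation_coupled <- row$translation_coupled
      }
      out
    }) |>
    dplyr::bind_rows()
}
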