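#' Measurement noise model for synthetic data
#'
#' Multiplicative lognormal noise for fluorescence and OD readings
#' (scale-proportional instrument noise) and additive Gaussian noise for
#' TE-table values (matching replicate-level TE scatter).
#'
#' @param fluor_sigma Lognormal sdlog applied to fluorescence readings.
#' @param od_sigma Lognormal sdlog applied to OD600 readings.
#' @param te_sigma Gaussian sd added to TE-table values.
#' @param replicates Number of replicates to generate (>= 1).
#' @param seed Integer seed.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(fluor_sigma = 0.02, od_sigma = 0.01, te_sigma = 0.02,
                        replicates = 3, seed = 1) {
  stopifnot(fluor_sigma >= 0, od_sigma >= 0, te_sigma >= 0, replicates >= 1)
  structure(list(fluor_sigma = fluor_sigma, od_sigma = od_sigma,
                 te_sigma = te_sigma, replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Build a construct panel emulating the W/R terminator-position series
#'
#' Emits a table of reporter constructs: a W-like series (natural upstream
#' sequence, distances spanning 8-48 nt), an R-like series (designed random
#' spacer, 9-59 nt), the terminator-free reference, and optionally uncoupled
#' variants (RBS and upstream ORF deleted, so no pioneer ribosome loads).
#' Ground-truth TEs come from the coupling model: coupled constructs get
#' `predict_te(d, series, params)`; uncoupled constructs get `te0` (ribosomal
#' repression abolished); the reference defines TE = 0.
#'
#' @param params A [coupling_params()] object supplying the ground truth.
#' @param w_distances,r_distances Integer spacer lengths for the two series.
#' @param include_uncoupled Add uncoupled (`translation_coupled = FALSE`)
#'   variants at the shortest and longest W distances.
#' @return A tibble of class `construct_panel`: `construct_id`, `series`,
#'   `distance_nt`, `rfp_modified`, `translation_coupled`, `is_reference`,
#'   `true_te`.
#' @export
make_construct_panel <- function(params = coupling_params(),
                                 w_distances = c(8, 13, 18, 23, 28, 33, 38, 43, 48),
                                 r_distances = c(9, 13, 17, 21, 25, 29, 33, 39, 45, 52, 59),
                                 include_uncoupled = TRUE) {
  stopifnot(inherits(params, "coupling_params"))
  w <- tibble::tibble(
    construct_id = paste0("W", w_distances),
    series = "W", distance_nt = as.integer(w_distances),
    rfp_modified = FALSE, translation_coupled = TRUE, is_reference = FALSE,
    true_te = predict_te(w_distances, "W", params)
  )
  r <- tibble::tibble(
    construct_id = paste0("R", r_distances),
    series = "R", distance_nt = as.integer(r_distances),
    rfp_modified = FALSE, translation_coupled = TRUE, is_reference = FALSE,
    true_te = predict_te(r_distances, "R", params)
  )
  ref <- tibble::tibble(
    construct_id = "I21", series = "other", distance_nt = NA_integer_,
    rfp_modified = FALSE, translation_coupled = TRUE, is_reference = TRUE,
    true_te = 0
  )
  panel <- dplyr::bind_rows(w, r, ref)
  if (include_uncoupled) {
    du <- as.integer(range(w_distances))
    unc <- tibble::tibble(
      construct_id = paste0("W", du, "-30U"),
      series = "W", distance_nt = du,
      rfp_modified = TRUE,          # RFP deleted: only the GFP channel reads out
      translation_coupled = FALSE, is_reference = FALSE,
      true_te = params$te0
    )
    panel <- dplyr::bind_rows(panel, unc)
  }
  class(panel) <- c("construct_panel", class(panel))
  panel
}

#' Generate plate-reader growth curves for a construct panel
#'
#' Emulates the measurement protocol: OD600 sampled every 30 minutes through
#' exponential growth, with two fluorescence channels. Fluorescence follows a
#' two-pool (immature -> mature, rate ln2/tau) balanced-growth model, which
#' under exponential growth makes measured fluorescence proportional to OD
#' with slope \eqn{f = P / (\mu (1 + \mu\tau/\ln 2))} — so the
#' maturation-corrected quantification recovers the generating synthesis rate
#' exactly. The construct's GFP synthesis rate is scaled by
#' \eqn{(1 - true\_te)} relative to the reference; RFP is at the reference
#' level for intact constructs, scaled by `rfp_scale` for `rfp_modified`
#' ones, and near zero for uncoupled constructs (no RFP translation).
#'
#' @param panel A construct table from [make_construct_panel()] (any data
#'   frame with its columns works).
#' @param mu Growth rate per minute.
#' @param od0 Inoculation OD600.
#' @param od_stop Stop sampling once OD exceeds this value.
#' @param sample_every Sampling cadence in minutes.
#' @param p_rfp_ref,p_gfp_ref Reference per-cell synthesis rates
#'   (fluorescence / OD / min) for the two channels.
#' @param tau_gfp,tau_rfp Maturation half-times (minutes); the quantifier
#'   must be run with the same values.
#' @param rfp_scale RFP expression scale for `rfp_modified` constructs with
#'   translation still coupled.
#' @param noise A [noise_model()].
#' @return A long measurements tibble: `construct_id`, `replicate`,
#'   `time_min`, `od600`, `f_rfp`, `f_gfp`.
#' @export
make_growth_series <- function(panel, mu = 0.01, od0 = 0.005, od_stop = 0.4,
                               sample_every = 30,
                               p_rfp_ref = 2000, p_gfp_ref = 1000,
                               tau_gfp = 15, tau_rfp = 40, rfp_scale = 0.6,
                               noise = noise_model()) {
  stopifnot(mu > 0, od0 > 0, p_rfp_ref > 0, p_gfp_ref > 0)
  if (any(panel$true_te > 1)) abort("true_te must be <= 1.")
  set.seed(noise$seed)
  t <- seq(0, ceiling(log(od_stop / od0) / mu), by = sample_every)
  od <- od0 * exp(mu * t)
  corr <- function(tau) 1 + mu * tau / log(2)  # maturation inflation factor
  purrr::pmap(panel, function(construct_id, true_te, rfp_modified,
                              translation_coupled, is_reference, ...) {
    p_gfp <- p_gfp_ref * (1 - true_te)
    p_rfp <- if (!translation_coupled) {
      1e-6 * p_rfp_ref               # RBS deleted: essentially no RFP signal
    } else if (rfp_modified) {
      rfp_scale * p_rfp_ref
    } else {
      p_rfp_ref
    }
    f_gfp_slope <- p_gfp / (mu * corr(tau_gfp))
    f_rfp_slope <- p_rfp / (mu * corr(tau_rfp))
    purrr::map(seq_len(noise$replicates), function(rep) {
      od_obs <- od * rlnorm(length(od), 0, noise$od_sigma)
      tibble::tibble(
        construct_id = construct_id,
        replicate = rep,
        time_min = t,
        od600 = od_obs,
        f_rfp = f_rfp_slope * od * rlnorm(length(od), 0, noise$fluor_sigma),
        f_gfp = f_gfp_slope * od * rlnorm(length(od), 0, noise$fluor_sigma)
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Generate a synthetic TE-distance table from the coupling model
#'
#' Evaluates the coupling model over the requested distances and adds i.i.d.
#' Gaussian noise per replicate — a stand-in for a measured TE-distance panel
#' with known ground truth, used for parameter-recovery checks.
#'
#' @param params A [coupling_params()] object.
#' @param distances Named list of integer distance vectors per series,
#'   e.g. `list(W = 5:48, R = 9:59)`.
#' @param sigma Gaussian sd of the TE noise.
#' @param replicates Replicates per distance.
#' @param seed Integer seed.
#' @return A tibble: `construct_id`, `series`, `distance_nt`, `replicate`,
#'   `te`, `true_te`.
#' @export
make_te_table <- function(params = coupling_params(),
                          distances = list(W = 5:48, R = 9:59),
                          sigma = 0.02, replicates = 3, seed = 1) {
  stopifnot(inherits(params, "coupling_params"), sigma >= 0, replicates >= 1)
  set.seed(seed)
  purrr::imap(distances, function(d, s) {
    tidyr::expand_grid(distance_nt = as.integer(d),
                       replicate = seq_len(replicates)) |>
      dplyr::mutate(
        series = s,
        construct_id = paste0(s, .data$distance_nt),
        true_te = predict_te(.data$distance_nt, s, params),
        te = .data$true_te + rnorm(dplyr::n(), 0, sigma)
      )
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("construct_id", "series", "distance_nt", "replicate",
                  "te", "true_te")
}
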