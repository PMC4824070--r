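#' Configuration for the coupled transcription-translation simulator
#'
#' Builds the transcript geometry and kinetic parameters for the mechanistic
#' simulator of one RNAP and the pioneer ribosome. The geometry mirrors the
#' dual-reporter construct: an RBS, an upstream ORF, a spacer of
#' `distance_nt` nt between the last base of the stop codon and the first nt
#' of the terminator hairpin stem, then the hairpin and U-tract; the
#' termination decision is taken when RNAP reaches the end of the U-tract.
#'
#' Footprints follow ribosome-profiling and RNAP-structure estimates: the
#' ribosome protects ~10 nt downstream of the A site
#' (`ribosome_downstream_protect`), RNAP sequesters ~12 nt of mRNA
#' (`rnap_mrna_protect` = 4-5 nt protected plus 7-8 nt in the DNA:RNA
#' hybrid). The default speeds make the free ribosome (15 codons/s = 45 nt/s)
#' intrinsically faster than RNAP (30 nt/s), and translation initiation takes
#' 1/`k_init` = 1.5 s on average.
#'
#' @param distance_nt Spacer length d (nt), non-negative integer.
#' @param orf_codons Length of the upstream ORF in codons (incl. stop).
#' @param rbs_end Last nt of the ribosome binding site.
#' @param hairpin_len,u_tract Hairpin and U-tract lengths (nt), which set the
#'   decision point downstream of the hairpin start.
#' @param k_rnap RNAP stepping rate, nt/s.
#' @param pause_sites Named numeric vector mapping transcript positions to
#'   RNAP stepping rates out of that position (pause = small rate), e.g.
#'   `c("350" = 2)`.
#' @param k_ribosome Ribosome stepping rate, codons/s.
#' @param ribosome_pause_sites Named numeric vector mapping A-site positions
#'   to ribosome stepping rates out of that position (translational pause =
#'   small rate). A pause lets the RNAP pull ahead, partially de-repressing a
#'   downstream terminator. Positions must lie on the ribosome's A-site frame
#'   (`start_codon + 3k`); off-frame positions are never visited.
#' @param k_init Translation initiation rate once the RBS is exposed, 1/s.
#' @param ribosome_footprint Total ribosome footprint on mRNA (nt; metadata,
#'   used by the `leading_edge` distance convention).
#' @param ribosome_downstream_protect nt protected downstream of the A site.
#' @param rnap_mrna_protect nt of mRNA sequestered by RNAP.
#' @param alpha,te0,readthrough_floor Termination parameters: on RNAP arrival
#'   the outcome is Bernoulli(`te0`) if the ribosome-hairpin distance X
#'   exceeds the occlusion threshold, else Bernoulli(`readthrough_floor`).
#' @param cdf_convention `"inclusive"` (repression iff X <= alpha) or
#'   `"strict"` (X <= alpha - 1); see [coupling_params()].
#' @param x_reference Ribosome reference point for X: `"a_site"` (default) or
#'   `"leading_edge"` (A site + downstream protection).
#' @param translation_enabled If `FALSE`, no ribosome ever loads (the
#'   uncoupled construct).
#' @param n_traj Default number of trajectories.
#' @param seed Default seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(distance_nt = 30, orf_codons = 231, rbs_end = 20,
                       hairpin_len = 24, u_tract = 8,
                       k_rnap = 30, pause_sites = NULL,
                       k_ribosome = 15, ribosome_pause_sites = NULL,
                       k_init = 1 / 1.5,
                       ribosome_footprint = 30,
                       ribosome_downstream_protect = 10,
                       rnap_mrna_protect = 12,
                       alpha = 27, te0 = 0.9, readthrough_floor = 0,
                       cdf_convention = c("inclusive", "strict"),
                       x_reference = c("a_site", "leading_edge"),
                       translation_enabled = TRUE,
                       n_traj = 10000, seed = 1) {
  cdf_convention <- match.arg(cdf_convention)
  x_reference <- match.arg(x_reference)
  stopifnot(distance_nt >= 0, distance_nt == round(distance_nt),
            orf_codons >= 2, rbs_end >= 1,
            k_rnap > 0, k_ribosome > 0, k_init > 0,
            ribosome_footprint > 0, ribosome_downstream_protect > 0,
            rnap_mrna_protect > 0,
            alpha >= 0, te0 >= 0, te0 <= 1,
            readthrough_floor >= 0, readthrough_floor <= 1,
            n_traj >= 1)
  start_codon <- rbs_end + 5L
  stop_codon_last <- start_codon + 3L * as.integer(orf_codons) - 1L
  hairpin_start <- stop_codon_last + as.integer(distance_nt) + 1L
  decision_point <- hairpin_start + as.integer(hairpin_len) + as.integer(u_tract)
  transcript_len <- decision_point + 50L
  for (ps in list(pause_sites, ribosome_pause_sites)) {
    if (!is.null(ps) && (is.null(names(ps)) || any(ps <= 0))) {
      abort("pause sites must be named vectors of positive rates keyed by position.")
    }
  }
  structure(
    list(
      distance_nt = as.integer(distance_nt),
      transcript_len = transcript_len, rbs_end = as.integer(rbs_end),
      start_codon = start_codon, stop_codon_last = stop_codon_last,
      hairpin_start = hairpin_start, decision_point = decision_point,
      k_rnap = k_rnap, pause_sites = pause_sites,
      k_ribosome = k_ribosome, ribosome_pause_sites = ribosome_pause_sites,
      k_init = k_init,
      ribosome_footprint = as.integer(ribosome_footprint),
      ribosome_downstream_protect = as.integer(ribosome_downstream_protect),
      rnap_mrna_protect = as.integer(rnap_mrna_protect),
      alpha = as.integer(alpha), te0 = te0,
      readthrough_floor = readthrough_floor,
      cdf_convention = cdf_convention, x_reference = x_reference,
      translation_enabled = isTRUE(translation_enabled),
      n_traj = as.integer(n_traj), seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Coupled transcription-translation simulator configuration\n")
  cat(sprintf("  geometry: RBS end %d | start %d | stop last %d | hairpin %d | decision %d (d = %d nt)\n",
              x$rbs_end, x$start_codon, x$stop_codon_last, x$hairpin_start,
              x$decision_point, x$distance_nt))
  cat(sprintf("  rates: RNAP %.1f nt/s, ribosome %.1f codons/s, init %.3f /s\n",
              x$k_rnap, x$k_ribosome, x$k_init))
  cat(sprintf("  termination: te0 = %.2f, alpha = %d (%s), floor = %.2f, translation %s\n",
              x$te0, x$alpha, x$cdf_convention, x$readthrough_floor,
              if (x$translation_enabled) "on" else "off"))
  invisible(x)
}

#' Simulate coupled RNAP-ribosome trajectories
#'
#' Runs the stochastic simulator: the RNAP advances 1 nt at a time (rate
#' `k_rnap`, position-specific at pause sites), the pioneer ribosome loads at
#' rate `k_init` once the RNAP has cleared the RBS and the ribosome's own
#' exclusion zone, then advances one codon at a time (rate `k_ribosome`)
#' unless sterically blocked by the RNAP or halted at the stop codon. When
#' the RNAP reaches the decision point, the ribosome-hairpin distance X is
#' recorded and the termination outcome is drawn: Bernoulli(`te0`) when the
#' ribosome is too far to occlude the hairpin (X above the threshold, or no
#' ribosome), Bernoulli(`readthrough_floor`) otherwise.
#'
#' @param config A [sim_config()].
#' @param n_traj,seed Override the config's trajectory count / seed.
#' @param check_invariants If `TRUE`, assert the steric-exclusion and
#'   stop-codon bounds after every event (slower; for testing).
#' @return A tibble of class `sim_samples` with one row per trajectory:
#'   `trajectory`, `x` (nt; `Inf` when no ribosome initiated), `terminated`,
#'   `head_start` (RNAP position minus RBS end at ribosome initiation),
#'   `catch_up_pos` (first A-site position where the ribosome, having
#'   advanced beyond its initiation site, was sterically blocked by the RNAP;
#'   `NA` if never). The config is attached as an attribute.
#' @export
simulate_coupling <- function(config, n_traj = config$n_traj,
                              seed = config$seed, check_invariants = FALSE) {
  stopifnot(inherits(config, "sim_config"), n_traj >= 1)
  k_rep <- .repression_k(config$alpha, config$cdf_convention)
  pp <- if (is.null(config$pause_sites)) integer(0) else
    as.integer(names(config$pause_sites))
  pr <- if (is.null(config$pause_sites)) numeric(0) else
    as.numeric(config$pause_sites)
  rpp <- if (is.null(config$ribosome_pause_sites)) integer(0) else
    as.integer(names(config$ribosome_pause_sites))
  rpr <- if (is.null(config$ribosome_pause_sites)) numeric(0) else
    as.numeric(config$ribosome_pause_sites)
  set.seed(seed)
  out <- simulate_trajectories_cpp(
    n_traj = as.integer(n_traj),
    rbs_end = config$rbs_end, start_codon = config$start_codon,
    stop_last = config$stop_codon_last, hairpin_start = config$hairpin_start,
    decision_point = config$decision_point,
    k_rnap = config$k_rnap, pause_pos = pp, pause_rate = pr,
    k_ribosome = config$k_ribosome,
    ribo_pause_pos = rpp, ribo_pause_rate = rpr,
    k_init = config$k_init,
    down_protect = config$ribosome_downstream_protect,
    rnap_protect = config$rnap_mrna_protect,
    translation_enabled = config$translation_enabled,
    te0 = config$te0, readthrough_floor = config$readthrough_floor,
    k_repress = as.integer(k_rep),
    check_invariants = isTRUE(check_invariants)
  )
  out <- tibble::as_tibble(out)
  if (config$x_reference == "leading_edge") {
    out$x <- out$x - config$ribosome_downstream_protect
  }
  attr(out, "config") <- config
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("sim_samples", class(out))
  out
}

#' Ribosome-hairpin distance distribution at RNAP arrival
#'
#' Integer-binned histogram of the recorded distances X over the finite
#' (ribosome-initiated) trajectories, plus sample moments.
#'
#' @param samples A `sim_samples` tibble from [simulate_coupling()], or a
#'   [sim_config()] (which is then simulated).
#' @param ... Passed to [simulate_coupling()] when `samples` is a config.
#' @return A tibble `x`, `count` with attributes `mean`, `variance`,
#'   `n_finite`, `n_infinite`.
#' @export
distance_distribution <- function(samples, ...) {
  if (inherits(samples, "sim_config")) samples <- simulate_coupling(samples, ...)
  x <- samples$x
  fin <- x[is.finite(x)]
  hist <- if (length(fin) > 0) {
    tibble::tibble(x = as.integer(names(table(fin))),
                   count = as.integer(table(fin)))
  } else {
    tibble::tibble(x = integer(0), count = integer(0))
  }
  attr(hist, "mean") <- if (length(fin)) mean(fin) else NA_real_
  attr(hist, "variance") <- if (length(fin) > 1) var(fin) else NA_real_
  attr(hist, "n_finite") <- length(fin)
  attr(hist, "n_infinite") <- sum(is.infinite(x))
  hist
}

#' Mechanistic termination-efficiency estimate
#'
#' Fraction of simulated trajectories that terminated, with the Wald
#' (binomial) standard error.
#'
#' @inheritParams distance_distribution
#' @return A one-row tibble: `te`, `se`, `n_traj`.
#' @export
te_from_simulation <- function(samples, ...) {
  if (inherits(samples, "sim_config")) samples <- simulate_coupling(samples, ...)
  n <- nrow(samples)
  if (n < 100) warn("fewer than 100 trajectories; the TE estimate is unstable.")
  p <- mean(samples$terminated)
  tibble::tibble(te = p, se = sqrt(p * (1 - p) / n), n_traj = n)
}

#' Poisson adequacy of the simulated distance distribution
#'
#' Fits a Poisson by method of moments (the sample mean of the finite
#' distances) and computes a chi-squared goodness-of-fit statistic with tail
#' bins pooled so every expected count is at least 5. Diagnostic output for
#' judging the Poisson approximation used by the analytic coupling model; the
#' mean-to-variance ratio is reported alongside (1 for an exact Poisson).
#'
#' @param samples A `sim_samples` tibble, or a numeric vector of distances.
#' @param min_expected Minimal expected count per pooled bin.
#' @return A one-row tibble: `lambda_hat`, `chisq`, `df`, `p_value`,
#'   `mean_var_ratio`, `n`.
#' @export
poisson_adequacy <- function(samples, min_expected = 5) {
  x <- if (is.data.frame(samples)) samples$x else samples
  fin <- x[is.finite(x)]
  if (length(fin) == 0) abort("no finite distance samples (translation never initiated?).")
  if (length(fin) < 100) abort("need >= 100 finite samples for the adequacy test.")
  if (any(fin < 0)) abort("distances must be non-negative for a Poisson fit.")
  lambda_hat <- mean(fin)
  v <- var(fin)
  ratio <- if (v > 0) lambda_hat / v else Inf
  if (!is.finite(ratio)) {
    warn("constant samples: variance 0, mean/variance ratio infinite.")
    return(tibble::tibble(lambda_hat = lambda_hat, chisq = NA_real_,
                          df = NA_integer_, p_value = NA_real_,
                          mean_var_ratio = Inf, n = length(fin)))
  }
  n <- length(fin)
  kmax <- max(fin)
  probs <- stats::dpois(0:kmax, lambda_hat)
  probs <- c(probs, max(0, 1 - sum(probs)))      # upper tail lumped
  expected <- n * probs
  observed <- c(tabulate(fin + 1, nbins = kmax + 1), 0)
  # pool adjacent bins until every expected count reaches the floor
  pooled_o <- c(); pooled_e <- c(); acc_o <- 0; acc_e <- 0
  for (i in seq_along(expected)) {
    acc_o <- acc_o + observed[i]; acc_e <- acc_e + expected[i]
    if (acc_e >= min_expected) {
      pooled_o <- c(pooled_o, acc_o); pooled_e <- c(pooled_e, acc_e)
      acc_o <- 0; acc_e <- 0
    }
  }
  if (acc_e > 0) {                               # fold remainder into last bin
    pooled_o[length(pooled_o)] <- pooled_o[length(pooled_o)] + acc_o
    pooled_e[length(pooled_e)] <- pooled_e[length(pooled_e)] + acc_e
  }
  chisq <- sum((pooled_o - pooled_e)^2 / pooled_e)
  df <- length(pooled_e) - 2L                    # 1 fitted parameter
  tibble::tibble(
    lambda_hat = lambda_hat, chisq = chisq, df = df,
    p_value = if (df > 0) pchisq(chisq, df, lower.tail = FALSE) else NA_real_,
    mean_var_ratio = ratio, n = n
  )
}

#' Head-start and catch-up summary
#'
#' Means over trajectories of the RNAP head start at ribosome initiation
#' (RNAP position minus RBS end) and of the first A-site position at which
#' the ribosome was sterically blocked by the RNAP. The expected head start
#' is the initiation gate offset plus `k_rnap / k_init` nt of transcription
#' during the exponential initiation wait.
#'
#' @inheritParams distance_distribution
#' @return A one-row tibble: `mean_head_start`, `mean_catch_up_pos`,
#'   `frac_caught_up`, `n_initiated`.
#' @export
head_start_and_catchup <- function(samples, ...) {
  if (inherits(samples, "sim_config")) samples <- simulate_coupling(samples, ...)
  hs <- samples$head_start[!is.na(samples$head_start)]
  cu <- samples$catch_up_pos[!is.na(samples$catch_up_pos)]
  tibble::tibble(
    mean_head_start = if (length(hs)) mean(hs) else NA_real_,
    mean_catch_up_pos = if (length(cu)) mean(cu) else NA_real_,
    frac_caught_up = if (nrow(samples)) length(cu) / sum(!is.na(samples$head_start)) else NA_real_,
    n_initiated = length(hs)
  )
}

#' Sweep the mechanistic TE over spacer distances
#'
#' Convenience wrapper: simulates `n_traj` trajectories at each distance and
#' returns the empirical TE curve.
#'
#' @param distances Integer spacer lengths to sweep.
#' @param n_traj Trajectories per distance.
#' @param seed Base seed; distance i uses `seed + i` so curves are paired
#'   across sweeps at the same seed.
#' @param ... Further arguments to [sim_config()].
#' @return A tibble: `distance_nt`, `te`, `se`, `n_traj`.
#' @export
sweep_te <- function(distances = seq(5, 50, by = 5), n_traj = 10000,
                     seed = 1, ...) {
  purrr::imap(as.integer(distances), function(d, i) {
    cfg <- sim_config(distance_nt = d, ...)
    dplyr::bind_cols(
      tibble::tibble(distance_nt = d),
      te_from_simulation(simulate_coupling(cfg, n_traj = n_traj, seed = seed + i))
    )
  }) |> dplyr::bind_rows()
}

#' Plot a simulated ribosome-hairpin distance distribution
#'
#' @param object A `sim_samples` tibble from [simulate_coupling()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sim_samples
#' @export
autoplot.sim_samples <- function(object, ...) {
  hist <- distance_distribution(object)
  cfg <- attr(object, "config")
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$x, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = cfg$alpha, linetype = "dashed") +
    ggplot2::labs(x = "ribosome-hairpin distance X at RNAP arrival (nt)",
                  y = "trajectories",
                  caption = "dashed line: occlusion threshold alpha") +
    ggplot2::theme_minimal()
}
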