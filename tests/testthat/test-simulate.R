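test_that("sim_config validates geometry and rates", {
  cfg <- sim_config(distance_nt = 30)
  expect_lt(cfg$rbs_end, cfg$start_codon)
  expect_lt(cfg$start_codon, cfg$stop_codon_last)
  expect_equal(cfg$hairpin_start - cfg$stop_codon_last - 1L, 30L)
  expect_lte(cfg$hairpin_start, cfg$decision_point)
  expect_error(sim_config(distance_nt = -1))
  expect_error(sim_config(k_rnap = 0))
  expect_error(sim_config(te0 = 1.5))
  expect_error(sim_config(pause_sites = c(5)), "named")
})

test_that("uncoupling translation abolishes ribosomal repression", {
  cfg <- sim_config(distance_nt = 8, translation_enabled = FALSE,
                    te0 = 0.9)
  s <- simulate_coupling(cfg, n_traj = 10000, seed = 11)
  expect_true(all(is.infinite(s$x)))
  est <- te_from_simulation(s)
  se <- sqrt(0.9 * 0.1 / 10000)
  expect_lt(abs(est$te - 0.9), 3 * se)
})

test_that("te0 = 0 gives zero termination exactly", {
  cfg <- sim_config(distance_nt = 40, te0 = 0)
  s <- simulate_coupling(cfg, n_traj = 500, seed = 2)
  expect_equal(sum(s$terminated), 0L)
})

test_that("the stop codon bounds the ribosome-hairpin distance", {
  cfg <- sim_config(distance_nt = 5)
  s <- simulate_coupling(cfg, n_traj = 5000, seed = 3, check_invariants = TRUE)
  fin <- s$x[is.finite(s$x)]
  expect_true(all(fin >= cfg$hairpin_start - cfg$stop_codon_last))
})

test_that("a distance beyond the occlusion threshold guarantees full efficiency", {
  # min X = d + 3 > alpha, so the ribosome can never occlude the hairpin
  cfg <- sim_config(distance_nt = 30, alpha = 27, te0 = 0.9)
  s <- simulate_coupling(cfg, n_traj = 10000, seed = 13)
  se <- sqrt(0.9 * 0.1 / 10000)
  expect_lt(abs(te_from_simulation(s)$te - 0.9), 3 * se)
})

test_that("empirical TE is non-decreasing in distance within noise", {
  sw <- sweep_te(distances = c(5, 12, 18, 22, 25, 28, 35, 45),
                 n_traj = 10000, seed = 17)
  for (i in seq_len(nrow(sw) - 1)) {
    slack <- 2 * (sw$se[i] + sw$se[i + 1])
    expect_gte(sw$te[i + 1], sw$te[i] - slack)
  }
  # proximal terminators are strongly repressed, distal ones near te0
  expect_lt(sw$te[1], 0.1)
  expect_gt(sw$te[nrow(sw)], 0.85)
})

test_that("slowing translation de-represses a proximal terminator", {
  fast <- te_from_simulation(
    simulate_coupling(sim_config(distance_nt = 5), n_traj = 6000, seed = 19))
  slow <- te_from_simulation(
    simulate_coupling(sim_config(distance_nt = 5, k_ribosome = 2),
                      n_traj = 6000, seed = 19))
  expect_gt(slow$te, fast$te + 3 * (fast$se + slow$se))
})

test_that("a translational pause site partially de-represses a proximal terminator", {
  cfg0 <- sim_config(distance_nt = 5)
  pause_at <- cfg0$stop_codon_last - 2 - 30        # on the A-site frame
  cfg_p <- sim_config(distance_nt = 5,
                      ribosome_pause_sites = stats::setNames(0.2, pause_at))
  base <- te_from_simulation(simulate_coupling(cfg0, n_traj = 6000, seed = 23))
  paused <- te_from_simulation(simulate_coupling(cfg_p, n_traj = 6000, seed = 23))
  expect_gt(paused$te, base$te + 3 * (base$se + paused$se))
  expect_lt(paused$te, 0.9)                         # partial, not full, recovery
})

test_that("an RNAP pause before the terminator lets the ribosome catch up", {
  cfg0 <- sim_config(distance_nt = 24)
  pause_at <- cfg0$hairpin_start - 5
  cfg_p <- sim_config(distance_nt = 24,
                      pause_sites = stats::setNames(0.5, pause_at))
  base <- te_from_simulation(simulate_coupling(cfg0, n_traj = 6000, seed = 29))
  paused <- te_from_simulation(simulate_coupling(cfg_p, n_traj = 6000, seed = 29))
  expect_lt(paused$te, base$te)
})

test_that("identical seed and config reproduce the trajectory set bit-for-bit", {
  cfg <- sim_config(distance_nt = 20)
  a <- simulate_coupling(cfg, n_traj = 2000, seed = 31)
  b <- simulate_coupling(cfg, n_traj = 2000, seed = 31)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_coupling(cfg, n_traj = 2000, seed = 32)
  expect_false(identical(a$x, c$x))
})

test_that("head start matches its closed-form expectation", {
  cfg <- sim_config(distance_nt = 30)
  gate <- max(cfg$rbs_end + cfg$rnap_mrna_protect,
              cfg$start_codon + 3 + cfg$ribosome_downstream_protect +
                cfg$rnap_mrna_protect)
  expected <- (gate - cfg$rbs_end) + cfg$k_rnap / cfg$k_init
  s <- simulate_coupling(cfg, n_traj = 8000, seed = 37)
  hs <- head_start_and_catchup(s)
  expect_lt(abs(hs$mean_head_start - expected), 2)

  # immediate initiation pins the head start at the gate offset
  cfg_fast <- sim_config(distance_nt = 30, k_init = 1e7)
  s2 <- simulate_coupling(cfg_fast, n_traj = 2000, seed = 38)
  hs2 <- head_start_and_catchup(s2)
  expect_lt(abs(hs2$mean_head_start - (gate - cfg$rbs_end)), 0.1)
})

test_that("the pioneer ribosome catches up within the reported window, or never when slower", {
  s <- simulate_coupling(sim_config(distance_nt = 30), n_traj = 5000, seed = 41)
  hs <- head_start_and_catchup(s)
  expect_gt(hs$frac_caught_up, 0.9)
  expect_gt(hs$mean_catch_up_pos, 100)
  expect_lt(hs$mean_catch_up_pos, 200)

  # a ribosome slower than the RNAP (in nt/s) never catches up once past the
  # initiation transient: any steric contact stays near the start codon
  cfg_slow <- sim_config(distance_nt = 30, k_ribosome = 5)
  s_slow <- simulate_coupling(cfg_slow, n_traj = 3000, seed = 43)
  hs_slow <- head_start_and_catchup(s_slow)
  expect_lt(hs_slow$frac_caught_up, 0.15)
  cu <- s_slow$catch_up_pos[!is.na(s_slow$catch_up_pos)]
  expect_equal(sum(cu > cfg_slow$start_codon + 100), 0L)
})

test_that("poisson_adequacy is calibrated on true Poisson draws and flags degeneracy", {
  set.seed(47)
  pvals <- replicate(25, {
    x <- rpois(2000, 33)
    poisson_adequacy(x)$p_value
  })
  # under the null the p-values are uniform: not piled on 0
  expect_lt(mean(pvals < 0.05), 0.25)
  expect_gt(mean(pvals), 0.2)

  expect_warning(res <- poisson_adequacy(rep(12, 500)), "constant")
  expect_equal(res$mean_var_ratio, Inf)
  expect_error(poisson_adequacy(rep(Inf, 500)), "no finite")
  expect_error(poisson_adequacy(rpois(50, 5)), ">= 100")
})

test_that("the simulated distance distribution is summarized faithfully", {
  cfg <- sim_config(distance_nt = 30)
  s <- simulate_coupling(cfg, n_traj = 5000, seed = 53)
  h <- distance_distribution(s)
  expect_equal(sum(h$count), attr(h, "n_finite"))
  expect_gte(attr(h, "mean"), 30)                  # stop-codon bound on the mean
  expect_gt(attr(h, "variance"), 0)
  expect_s3_class(autoplot(s), "ggplot")
})
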