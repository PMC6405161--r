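p_def <- model_params()

test_that("uncoupled fixed point solves the equilibrium cubic", {
  # direct substitution case: x0 = -3.025 gives x = -2, z = 4.1
  fp <- uncoupled_fixed_point(-3.025)
  expect_equal(fp$x_bar, -2, tolerance = 1e-12)
  expect_equal(fp$z_bar, 4.1, tolerance = 1e-12)

  # independent bisection oracle for x0 = -2.2
  cubic <- function(x) x^3 + 2 * x^2 + 4 * x + 4.7
  oracle <- stats::uniroot(cubic, c(-2, -1), tol = 1e-14)$root
  expect_equal(uncoupled_fixed_point(-2.2)$x_bar, oracle, tolerance = 1e-10)

  # construction identity z = -x^3 - 2x^2 + 1 + I, vectorized
  x0s <- seq(-3, -1.5, by = 0.25)
  fps <- uncoupled_fixed_point(x0s)
  expect_equal(fps$z_bar,
               -fps$x_bar^3 - 2 * fps$x_bar^2 + 1 + p_def$I_ext,
               tolerance = 1e-12)
})

test_that("network fixed point reduces to per-node roots when uncoupled and has tiny residual", {
  cn0 <- connectome(matrix(0, 5, 5))
  ex <- excitability_map(c(-2.2, -2.3, -1.6, -2.5, -2.1000001))
  fp <- network_fixed_point(cn0, ex)
  expect_true(fp$converged)
  expect_equal(fp$x_bar, uncoupled_fixed_point(ex$x0)$x_bar, tolerance = 1e-10)

  cn <- generate_modular(synth_params(n_nodes = 10, seed = 6))
  ex2 <- excitability_from_ez(10, ez = 3)
  fp2 <- network_fixed_point(cn, ex2)
  expect_true(fp2$converged)
  # plug the solution back into the algebraic system
  K <- cn$weights
  s <- rowSums(K)
  res <- 4 * (fp2$x_bar - ex2$x0) - fp2$z_bar -
    (as.vector(K %*% fp2$x_bar) - s * fp2$x_bar)
  expect_lt(max(abs(res)), 1e-10)
})

test_that("all-healthy planted networks have every node on the healthy branch", {
  sc <- generate_planted(20, 2, seed = 3)
  ex <- excitability_from_ez(20, ez = integer(0))
  fp <- network_fixed_point(sc$connectome, ex)
  expect_true(fp$converged)
  expect_true(all(fp$x_bar < -4 / 3))
})

test_that("a converged stable fixed point is invariant under simulation", {
  cn <- generate_modular(synth_params(n_nodes = 10, seed = 2))
  ex <- excitability_from_ez(10, ez = integer(0))
  fp <- network_fixed_point(cn, ex)
  traj <- simulate_epileptor(cn, ex, init = c(fp$x_bar, fp$z_bar))
  expect_lt(max(abs(sweep(traj$x, 2, fp$x_bar))), 1e-6)
  expect_lt(max(abs(sweep(traj$z, 2, fp$z_bar))), 1e-6)
})

test_that("a single uncoupled epileptogenic node oscillates with period of order tau", {
  cn <- connectome(matrix(0, 1, 1))
  ex <- excitability_map(-1.6)
  traj <- simulate_epileptor(cn, ex)
  ras <- detect_seizure_events(traj)
  expect_gte(nrow(ras), 2)
  isi <- diff(ras$onset)
  expect_true(all(isi > 0.1 * p_def$tau & isi < 10 * p_def$tau))
  # recurrently exceeds 0
  expect_gt(sum(diff(traj$x[, 1] > 0) == 1), 1)
})

test_that("trajectories are deterministic and integrator back-ends agree", {
  cn <- connectome(matrix(0, 1, 1))
  ex <- excitability_map(-1.6)
  t1 <- simulate_epileptor(cn, ex, horizon = 300, dt_out = 1)
  t2 <- simulate_epileptor(cn, ex, horizon = 300, dt_out = 1)
  expect_identical(t1$x, t2$x)
  t_rk4 <- simulate_epileptor(cn, ex, horizon = 300, dt_out = 1,
                              method = "rk4", dt_fixed = 0.02)
  t_lsoda <- simulate_epileptor(cn, ex, horizon = 300, dt_out = 1,
                                method = "lsoda")
  expect_lt(max(abs(t1$x - t_rk4$x)), 1e-3)
  expect_lt(max(abs(t1$x - t_lsoda$x)), 1e-3)
})

test_that("event detection applies hysteresis thresholds and a duration floor", {
  tt <- 0:100
  # constant below threshold: nothing
  flat <- fake_trajectory(tt, matrix(-2, 101, 1))
  expect_equal(nrow(detect_seizure_events(flat)), 0)

  # square wave crossing 0 twice: exactly two events with known onsets
  x <- rep(-2, 101)
  x[11:31] <- 1    # t = 10..30
  x[61:81] <- 1    # t = 60..80
  sq <- fake_trajectory(tt, matrix(x, 101, 1))
  ras <- detect_seizure_events(sq)
  expect_equal(nrow(ras), 2)
  expect_equal(ras$onset, c(10, 60))
  expect_true(all(ras$offset > ras$onset))

  # a 2-sample blip is removed by the duration floor
  blip <- rep(-2, 101)
  blip[50:51] <- 1
  expect_equal(nrow(detect_seizure_events(fake_trajectory(tt, matrix(blip, 101, 1)),
                                          min_duration = 5)), 0)

  expect_error(detect_seizure_events(flat, theta_on = -1, theta_off = 0),
               "theta_off")
})

test_that("uncoupled EZ seizures stay on the EZ node and recruited_set excludes the EZ", {
  cn <- connectome(matrix(0, 4, 4))
  ex <- excitability_from_ez(4, ez = 2)
  traj <- simulate_epileptor(cn, ex)
  ras <- detect_seizure_events(traj)
  expect_true(all(ras$node == 2))
  expect_length(recruited_set(ras, ez = 2), 0)
  # empty raster is valid input
  empty <- detect_seizure_events(fake_trajectory(0:10, matrix(-2, 11, 2)))
  expect_length(recruited_set(empty, ez = 1), 0)
})

test_that("signal-energy PZ criterion keeps channels at or above 30% of max energy", {
  fs <- 500
  tt <- seq(0, 2, by = 1 / fs)
  base <- sin(2 * pi * 10 * tt)
  # scalar multiples of one in-band waveform: filtering preserves exact ratios
  sig <- rbind(base, sqrt(0.4) * base, sqrt(0.2) * base)
  expect_equal(pz_from_signal_energy(sig, fs, ez_channels = 1), 2L,
               ignore_attr = TRUE)
  # boundary: a channel sitting exactly at the threshold fraction is included
  # ("at least 30%"): recover the realized energies, then threshold exactly there
  sig2 <- rbind(base, sqrt(0.3) * base)
  e <- attr(pz_from_signal_energy(sig2, fs), "energy")
  expect_equal(pz_from_signal_energy(sig2, fs, energy_fraction = e[2] / e[1]),
               c(1L, 2L), ignore_attr = TRUE)
  # all channels in the EZ: empty result
  expect_length(pz_from_signal_energy(sig, fs, ez_channels = 1:3), 0)
  expect_error(pz_from_signal_energy(sig, fs = 80), "100")
  expect_error(pz_from_signal_energy(matrix(0, 0, 0), fs = 500), "non-empty")
})
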