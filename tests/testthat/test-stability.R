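p_def <- model_params()

test_that("the Jacobian matches its closed block structure", {
  # single node at x_bar = -2: J = [[-4, -1], [4/tau, -1/tau]]
  cn <- connectome(matrix(0, 1, 1))
  ex <- excitability_map(-3.025)
  fp <- network_fixed_point(cn, ex)
  J <- build_jacobian(cn, fp)
  expect_equal(unclass(J)[1:2, 1:2],
               matrix(c(-4, 4 / 2857, -1, -1 / 2857), 2, 2),
               tolerance = 1e-10, ignore_attr = TRUE)

  # hand-set coupling entry: z-row off-diagonal is -K_ij / tau
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5
  cn2 <- connectome(w)
  ex2 <- excitability_map(rep(-2.2, 3))
  J2 <- build_jacobian(cn2, network_fixed_point(cn2, ex2))
  expect_equal(J2[4, 2], -0.5 / 2857)
  expect_equal(J2[4, 1], (4 + 0.5) / 2857)

  bad <- structure(list(x_bar = rep(-2, 3), z_bar = rep(4, 3),
                        residual_norm = 1, converged = FALSE, iterations = 100),
                   class = "fixed_point")
  expect_error(build_jacobian(cn2, bad), "converge")
})

test_that("the Jacobian agrees with central finite differences on random instances", {
  for (s in 1:5) {
    n <- 4 + s
    cn <- generate_modular(synth_params(n_nodes = n, n_modules = 2,
                                        p_within = 0.8, p_between = 0.3,
                                        seed = s))
    ez <- if (s %% 2 == 0) sample.int(n, 1) else integer(0)
    ex <- excitability_from_ez(n, ez)
    fp <- network_fixed_point(cn, ex)
    expect_true(fp$converged)
    J <- build_jacobian(cn, fp)
    f <- oracle_field(cn$weights, ex$x0, p_def$tau, p_def$I_ext)
    Jfd <- fd_jacobian(f, c(fp$x_bar, fp$z_bar))
    expect_lt(max(abs(J - Jfd)) / max(abs(J)), 1e-6)
  }
})

test_that("decoupled spectra equal the union of per-node closed forms", {
  x0s <- c(-2.2, -2.4, -1.6, -2.15, -3.0, -2.05)
  cn <- connectome(matrix(0, 6, 6))
  ex <- excitability_map(x0s)
  fp <- network_fixed_point(cn, ex)
  rep <- eigen_analysis(build_jacobian(cn, fp))
  closed <- unlist(lapply(fp$x_bar, node_spectrum_closed))
  ord <- order(-Re(closed), -Im(closed))
  got_ord <- order(-Re(rep$eigenvalues), -Im(rep$eigenvalues))
  expect_lt(max(Mod(rep$eigenvalues[got_ord] - closed[ord])), 1e-10)
  # contract: sorted non-increasing real parts
  expect_true(all(diff(Re(rep$eigenvalues)) <= 1e-12))
  # unit-norm eigenvector
  expect_equal(sum(Mod(rep$max_eigenvector)^2), 1, tolerance = 1e-12)
})

test_that("positive eigenvalue counts reflect the single-node stability band", {
  # all healthy, uncoupled: every 2x2 block stable
  cn <- connectome(matrix(0, 4, 4))
  ex_h <- excitability_from_ez(4, integer(0))
  rep_h <- eigen_analysis(build_jacobian(cn, network_fixed_point(cn, ex_h)))
  expect_equal(rep_h$n_positive, 0)

  # one epileptogenic node: exactly its unstable pair, scores localized there
  ex_e <- excitability_from_ez(4, ez = 3)
  rep_e <- eigen_analysis(build_jacobian(cn, network_fixed_point(cn, ex_e)))
  expect_equal(rep_e$n_positive, 2)
  expect_equal(which.max(rep_e$node_scores), 3)
  expect_lt(max(rep_e$node_scores[-3]), 1e-10)
})

test_that("PZ prediction is empty when uncoupled and recovers planted links ranked by weight", {
  cn <- connectome(matrix(0, 4, 4))
  ex <- excitability_from_ez(4, ez = 2)
  rep0 <- eigen_analysis(build_jacobian(cn, network_fixed_point(cn, ex)))
  expect_length(predict_pz(rep0, ez = 2), 0)

  sc <- generate_planted(30, 3, seed = 4)
  exs <- excitability_from_ez(30, sc$ez)
  fps <- network_fixed_point(sc$connectome, exs)
  reps <- eigen_analysis(build_jacobian(sc$connectome, fps))
  pz <- predict_pz(reps, sc$ez)
  # exactly the planted nodes, ranked by planted weight
  expect_equal(as.integer(pz), sc$planted_edges[, "pz"])
  # relative mode thresholds against the largest non-EZ score
  fake <- structure(list(eigenvalues = complex(real = c(1, -1)),
                         n_positive = 1L,
                         max_eigenvector = complex(4),
                         node_scores = c(0.9, 0.5, 0.04, 0.001), n = 4L),
                    class = "stability_report")
  expect_equal(as.integer(predict_pz(fake, ez = 1, eps_loc = 0.05,
                                     mode = "relative")), c(2L, 3L))
})

test_that("the Lyapunov exponent matches linear theory at a stable fixed point", {
  cn <- connectome(matrix(0, 1, 1))
  ex <- excitability_map(-2.2)
  lam <- max(Re(eigen_analysis(build_jacobian(cn, network_fixed_point(cn, ex)))$eigenvalues))
  ly <- max_lyapunov(cn, ex, horizon = 10000)
  expect_lt(lam, 0)
  expect_lt(abs(ly$exponent - lam) / abs(lam), 0.05)
  # halving the renormalization interval barely moves the estimate
  ly2 <- max_lyapunov(cn, ex, horizon = 10000, renorm_interval = 25)
  expect_lt(abs(ly2$exponent - ly$exponent) / abs(ly$exponent), 0.01)
})

test_that("Lyapunov-vector localization ranks the same nodes as the eigenvector scores", {
  sc <- generate_planted(30, 3, seed = 5)
  ex <- excitability_from_ez(30, sc$ez)
  ly <- max_lyapunov(sc$connectome, ex, horizon = 10 * p_def$tau)
  rep <- eigen_analysis(build_jacobian(sc$connectome,
                                       network_fixed_point(sc$connectome, ex)))
  k <- length(sc$planted_pz) + 1
  expect_setequal(order(-ly$profile)[1:k], order(-rep$node_scores)[1:k])
})
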