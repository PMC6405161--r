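#' Epileptor model parameters
#'
#' The two-dimensional Epileptor reduction keeps one fast variable `x` per
#' region (bistable between a healthy node and ictal oscillation) and one slow
#' permittivity variable `z` that drives the autonomous alternation between
#' interictal and ictal states:
#' \deqn{\dot x_i = -x_i^3 - 2x_i^2 + 1 - z_i + I}
#' \deqn{\dot z_i = \frac{1}{\tau}\left[4(x_i - x_{0,i}) - z_i -
#'   \sum_j K_{ij}(x_j - x_i)\right]}
#'
#' @param tau timescale separation between fast and slow dynamics
#'   (dimensionless, default 2857).
#' @param I_ext passive current setting the operating point (default 3.1).
#' @param x_c critical excitability separating epileptogenic (`x0 > x_c`) from
#'   healthy (`x0 < x_c`) regions (default -2.1).
#' @return object of class `model_params`.
#' @export
model_params <- function(tau = 2857, I_ext = 3.1, x_c = -2.1) {
  if (!is.finite(tau) || tau <= 1) stop("tau must be > 1", call. = FALSE)
  if (!is.finite(I_ext)) stop("I_ext must be finite", call. = FALSE)
  structure(list(tau = tau, I_ext = I_ext, x_c = x_c), class = "model_params")
}

#' Per-node excitability map
#'
#' A node is epileptogenic (EZ) iff its excitability exceeds the critical
#' value, `x0 > x_c`; such nodes trigger seizures autonomously while all other
#' nodes rest at a stable equilibrium.
#'
#' @param x0 numeric vector of N excitability values.
#' @param params a [model_params()] (supplies `x_c`).
#' @return object of class `excitability_map` with fields `x0`, `ez`.
#' @seealso [excitability_from_ez()] for the common two-level assignment.
#' @export
excitability_map <- function(x0, params = model_params()) {
  if (!is.numeric(x0) || any(!is.finite(x0)))
    stop("x0 must be a finite numeric vector", call. = FALSE)
  structure(list(x0 = as.numeric(x0),
                 ez = which(x0 > params$x_c)),
            class = "excitability_map")
}

#' Two-level excitability assignment
#'
#' The usual clinical hypothesis: a small epileptogenic set at elevated
#' excitability, everything else at a single healthy level.
#'
#' @param n number of regions.
#' @param ez EZ node indices (may be empty).
#' @param x0_ez excitability of EZ nodes (default -1.6, above `x_c`).
#' @param x0_healthy excitability of all other nodes (default -2.2).
#' @param params a [model_params()].
#' @return an [excitability_map()].
#' @export
excitability_from_ez <- function(n, ez = integer(0), x0_ez = -1.6,
                                 x0_healthy = -2.2, params = model_params()) {
  ez <- as.integer(ez)
  if (any(ez < 1 | ez > n)) stop("ez indices out of range", call. = FALSE)
  x0 <- rep(x0_healthy, n)
  x0[ez] <- x0_ez
  excitability_map(x0, params)
}

#' Fixed point of an isolated Epileptor node
#'
#' With no coupling the equilibrium condition reduces to the cubic
#' \eqn{x^3 + 2x^2 + 4x - (1 + I + 4 x_0) = 0}, whose derivative
#' \eqn{3x^2 + 4x + 4} is strictly positive, so the real root is unique;
#' then \eqn{z = 4(x - x_0)}.
#'
#' @param x0 excitability value(s); vectorized.
#' @param params a [model_params()].
#' @return list with numeric vectors `x_bar`, `z_bar`.
#' @examples
#' uncoupled_fixed_point(-3.025)  # x_bar = -2, z_bar = 4.1
#' @export
uncoupled_fixed_point <- function(x0, params = model_params()) {
  stopifnot(is.numeric(x0), all(is.finite(x0)))
  x_bar <- vapply(x0, function(v) {
    r <- polyroot(c(-(1 + params$I_ext + 4 * v), 4, 2, 1))
    xr <- Re(r)[which.min(abs(Im(r)))]
    # one Newton polish for full double precision
    for (it in 1:3) {
      f <- xr^3 + 2 * xr^2 + 4 * xr - (1 + params$I_ext + 4 * v)
      xr <- xr - f / (3 * xr^2 + 4 * xr + 4)
    }
    xr
  }, 0.0)
  list(x_bar = x_bar, z_bar = 4 * (x_bar - x0))
}

#' Fixed point of the coupled network
#'
#' Solves, per node, \eqn{4(x_i - x_{0,i}) - z_i(x_i) - \sum_j K_{ij}(x_j -
#' x_i) = 0} with \eqn{z_i(x_i) = -x_i^3 - 2x_i^2 + 1 + I}, by damped Newton
#' iteration started from the uncoupled roots. The returned `z_bar` satisfies
#' the `x`-nullcline identity exactly by construction.
#'
#' @param c a `connectome`.
#' @param ex an [excitability_map()] of matching length.
#' @param params a [model_params()].
#' @param tol max-norm residual tolerance.
#' @param max_iter maximum Newton iterations.
#' @return object of class `fixed_point`: `x_bar`, `z_bar`, `residual_norm`,
#'   `converged`, `iterations`. Non-convergence is reported explicitly via
#'   `converged = FALSE`, never as a silent wrong answer.
#' @export
network_fixed_point <- function(c, ex, params = model_params(),
                                tol = 1e-12, max_iter = 100) {
  stopifnot(inherits(c, "connectome"), inherits(ex, "excitability_map"))
  K <- c$weights
  n <- nrow(K)
  if (length(ex$x0) != n)
    stop("excitability map length does not match connectome size", call. = FALSE)
  x0 <- ex$x0
  s <- rowSums(K)
  I <- params$I_ext
  Fres <- function(x)
    4 * (x - x0) - (-x^3 - 2 * x^2 + 1 + I) - (as.vector(K %*% x) - s * x)
  x <- uncoupled_fixed_point(x0, params)$x_bar
  f <- Fres(x)
  it <- 0L
  converged <- max(abs(f)) < tol
  while (!converged && it < max_iter) {
    it <- it + 1L
    J <- -K
    diag(J) <- 4 + 3 * x^2 + 4 * x + s
    dx <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(dx)) break
    lambda <- 1
    repeat {
      xn <- x - lambda * dx
      fn <- Fres(xn)
      if (max(abs(fn)) < max(abs(f)) || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    if (max(abs(fn)) >= max(abs(f))) break  # no progress even fully damped
    x <- xn
    f <- fn
    converged <- max(abs(f)) < tol
  }
  structure(list(x_bar = x, z_bar = -x^3 - 2 * x^2 + 1 + I,
                 residual_norm = max(abs(f)), converged = converged,
                 iterations = it),
            class = "fixed_point")
}

#' @export
print.fixed_point <- function(x, ...) {
  cat(sprintf("fixed point (%d nodes): %s, residual %.3g after %d iterations\n",
              length(x$x_bar), if (x$converged) "converged" else "NOT converged",
              x$residual_norm, x$iterations))
  invisible(x)
}

#' Simulate the coupled Epileptor network
#'
#' Deterministic integration of the autonomous system. The default initial
#' condition is the healthy-branch fixed point of the all-healthy system
#' (every `x0` clamped at the healthy reference level), so epileptogenic nodes
#' drift into seizure through their own slow permittivity dynamics.
#'
#' @param c a `connectome`.
#' @param ex an [excitability_map()].
#' @param params a [model_params()].
#' @param horizon simulated duration (model time units); default `10 * tau` so
#'   several seizure cycles fit.
#' @param dt_out output sampling step.
#' @param init `"fixed_point"` (default) or a numeric state vector
#'   `c(x, z)` of length 2N.
#' @param method `"rk45"` (adaptive Cash-Karp, default), `"rk4"` (fixed-step
#'   cross-check) or `"lsoda"` (via \pkg{deSolve}).
#' @param rtol,atol adaptive tolerances.
#' @param dt_fixed step for `method = "rk4"`.
#' @param h_max maximum internal step for the adaptive methods.
#' @param watch optional node indices monitored for early termination: the run
#'   stops as soon as any watched node's `x` exceeds `theta_watch`.
#' @param theta_watch threshold for `watch` (default 0).
#' @param x0_healthy_ref healthy reference excitability used to build the
#'   default initial condition.
#' @return object of class `epi_trajectory`: list with `times`, matrices `x`
#'   and `z` (rows = samples, columns = nodes), `stopped`, `t_stop`.
#' @export
simulate_epileptor <- function(c, ex, params = model_params(),
                               horizon = 10 * params$tau, dt_out = 5,
                               init = "fixed_point", method = c("rk45", "rk4", "lsoda"),
                               rtol = 1e-8, atol = 1e-8, dt_fixed = 0.05,
                               h_max = 25, watch = integer(0), theta_watch = 0,
                               x0_healthy_ref = -2.2) {
  stopifnot(inherits(c, "connectome"), inherits(ex, "excitability_map"))
  method <- match.arg(method)
  if (!is.finite(horizon) || horizon <= 0) stop("horizon must be > 0", call. = FALSE)
  K <- c$weights
  n <- nrow(K)
  if (length(ex$x0) != n)
    stop("excitability map length does not match connectome size", call. = FALSE)
  if (identical(init, "fixed_point")) {
    hp <- uncoupled_fixed_point(pmin(ex$x0, x0_healthy_ref), params)
    y0 <- c(hp$x_bar, hp$z_bar)
  } else {
    y0 <- as.numeric(init)
    if (length(y0) != 2 * n) stop("init state must have length 2N", call. = FALSE)
    if (any(!is.finite(y0))) stop("init state must be finite", call. = FALSE)
  }
  if (method == "lsoda") {
    s <- rowSums(K)
    rhs <- function(t, y, p) {
      x <- y[1:n]; z <- y[(n + 1):(2 * n)]
      dx <- -x^3 - 2 * x^2 + 1 - z + params$I_ext
      dz <- (4 * (x - ex$x0) - z - (as.vector(K %*% x) - s * x)) / params$tau
      list(c(dx, dz))
    }
    out <- deSolve::lsoda(y0, seq(0, horizon, by = dt_out), rhs, NULL,
                          rtol = rtol, atol = atol)
    if (any(!is.finite(out)))
      stop("integration failure (non-finite state)", call. = FALSE)
    res <- list(times = out[, 1], y = unname(out[, -1, drop = FALSE]),
                stopped = FALSE, t_stop = NA_real_)
  } else {
    res <- cpp_integrate(K, ex$x0, params$tau, params$I_ext, y0, 0, horizon,
                         dt_out, rtol, atol, as.integer(watch), theta_watch,
                         method, dt_fixed, h_max)
  }
  structure(list(times = res$times,
                 x = res$y[, 1:n, drop = FALSE],
                 z = res$y[, (n + 1):(2 * n), drop = FALSE],
                 stopped = isTRUE(res$stopped), t_stop = res$t_stop,
                 horizon = horizon, labels = c$labels),
            class = "epi_trajectory")
}

#' @export
print.epi_trajectory <- function(x, ...) {
  cat(sprintf("epileptor trajectory: %d nodes, %d samples over t in [0, %g]%s\n",
              ncol(x$x), length(x$times), max(x$times),
              if (x$stopped) sprintf(" (stopped early at t = %g)", x$t_stop) else ""))
  invisible(x)
}

#' Detect per-node seizure events in a trajectory
#'
#' Hysteresis thresholding of the fast variable: an event opens at an upward
#' crossing of `theta_on` and closes at a downward crossing of `theta_off`;
#' events shorter than `min_duration` are discarded. Defaults separate the two
#' branches of the cubic nullcline unambiguously: healthy equilibria satisfy
#' `x < -4/3` while ictal oscillation visits `x > 0`. An event still open at
#' the end of the trajectory is closed at the final sample.
#'
#' @param traj an `epi_trajectory`.
#' @param theta_on,theta_off on/off thresholds (`theta_off < theta_on`).
#' @param min_duration minimum event duration (model time units).
#' @return object of class `seizure_raster`: data.frame with columns `node`,
#'   `onset`, `offset`, sorted by onset, with attribute `horizon`.
#' @export
detect_seizure_events <- function(traj, theta_on = 0, theta_off = -1,
                                  min_duration = 5) {
  stopifnot(inherits(traj, "epi_trajectory"))
  if (!(theta_off < theta_on)) stop("theta_off must be < theta_on", call. = FALSE)
  tt <- traj$times
  ev <- vector("list", ncol(traj$x))
  for (i in seq_len(ncol(traj$x))) {
    xi <- traj$x[, i]
    on <- which(xi[-1] > theta_on & xi[-length(xi)] <= theta_on) + 1L
    if (length(on) == 0) next
    rows <- list()
    state_open_until <- -Inf
    for (o in on) {
      if (tt[o] <= state_open_until) next  # still inside the previous event
      rest <- which(xi < theta_off & seq_along(xi) > o)
      off <- if (length(rest) > 0) rest[1] else length(xi)
      rows[[length(rows) + 1L]] <- c(tt[o], tt[off])
      state_open_until <- tt[off]
    }
    m <- do.call(rbind, rows)
    keep <- (m[, 2] - m[, 1]) >= min_duration
    m <- m[keep, , drop = FALSE]
    if (nrow(m) > 0)
      ev[[i]] <- data.frame(node = i, onset = m[, 1], offset = m[, 2])
  }
  ev <- ev[!vapply(ev, is.null, TRUE)]
  raster <- if (length(ev) > 0) do.call(rbind, ev)
            else data.frame(node = integer(0), onset = numeric(0), offset = numeric(0))
  raster <- raster[order(raster$onset, raster$node), , drop = FALSE]
  rownames(raster) <- NULL
  structure(raster, horizon = max(tt), class = c("seizure_raster", "data.frame"))
}

#' Non-EZ nodes recruited into seizure activity
#'
#' @param raster a `seizure_raster`.
#' @param ez EZ node indices to exclude.
#' @return integer vector of recruited nodes ordered by first onset, with
#'   attribute `first_onset` giving the onset times.
#' @export
recruited_set <- function(raster, ez) {
  stopifnot(inherits(raster, "seizure_raster"))
  r <- raster[!(raster$node %in% ez), , drop = FALSE]
  if (nrow(r) == 0)
    return(structure(integer(0), first_onset = numeric(0)))
  first <- tapply(r$onset, r$node, min)
  ord <- order(first)
  structure(as.integer(names(first))[ord],
            first_onset = as.numeric(first)[ord])
}

#' Propagation zone from multichannel signal energy
#'
#' The clinical criterion: band-pass each channel at 1-50 Hz (Butterworth
#' order 4, applied forward-backward for zero phase), compute the energy as
#' the sum of squared filtered samples, and flag every non-EZ channel whose
#' energy is at least 30% of the maximum channel energy.
#'
#' @param signals numeric matrix, channels x samples.
#' @param fs sampling rate in Hz; must exceed 100 so the 50 Hz band edge is
#'   below Nyquist.
#' @param ez_channels channel indices excluded from the result.
#' @param energy_fraction inclusion threshold as a fraction of the maximum
#'   energy (default 0.30; the boundary case is included).
#' @return integer vector of PZ channel indices, with attribute `energy`
#'   giving all channel energies.
#' @export
pz_from_signal_energy <- function(signals, fs, ez_channels = integer(0),
                                  energy_fraction = 0.30) {
  if (!is.matrix(signals) || nrow(signals) < 1 || ncol(signals) < 1)
    stop("signals must be a non-empty channels x samples matrix", call. = FALSE)
  if (!is.finite(fs) || fs <= 100)
    stop("sampling rate must exceed 100 Hz (50 Hz band edge below Nyquist)",
         call. = FALSE)
  bf <- signal::butter(4, c(1, 50) / (fs / 2), type = "pass")
  energy <- apply(signals, 1, function(ch) {
    f <- signal::filtfilt(bf, ch)
    sum(f^2)
  })
  keep <- which(energy >= energy_fraction * max(energy))
  structure(as.integer(setdiff(keep, ez_channels)), energy = energy)
}
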