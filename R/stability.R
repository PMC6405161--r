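#' Jacobian of the coupled Epileptor network at a fixed point
#'
#' The 2N x 2N Jacobian, state ordered as (x-block, z-block):
#' x-rows have \eqn{\partial \dot x_i/\partial x_i = -3\bar x_i^2 - 4\bar x_i}
#' and \eqn{\partial \dot x_i/\partial z_i = -1}; z-rows have
#' \eqn{\partial \dot z_i/\partial x_i = (4 + \sum_j K_{ij})/\tau},
#' \eqn{\partial \dot z_i/\partial x_j = -K_{ij}/\tau} and
#' \eqn{\partial \dot z_i/\partial z_i = -1/\tau}.
#'
#' @param c a `connectome`.
#' @param fp a converged [network_fixed_point()].
#' @param params a [model_params()].
#' @return a 2N x 2N numeric matrix with attributes `n` (node count) and
#'   `fixed_point`.
#' @export
build_jacobian <- function(c, fp, params = model_params()) {
  stopifnot(inherits(c, "connectome"), inherits(fp, "fixed_point"))
  if (!isTRUE(fp$converged))
    stop("fixed point did not converge; refusing to build the Jacobian",
         call. = FALSE)
  K <- c$weights
  n <- nrow(K)
  if (length(fp$x_bar) != n)
    stop("fixed point length does not match connectome size", call. = FALSE)
  x <- fp$x_bar
  tau <- params$tau
  J <- matrix(0, 2 * n, 2 * n)
  J[cbind(1:n, 1:n)] <- -3 * x^2 - 4 * x
  J[cbind(1:n, (n + 1):(2 * n))] <- -1
  J[(n + 1):(2 * n), 1:n] <- -K / tau
  J[cbind((n + 1):(2 * n), 1:n)] <- (4 + rowSums(K)) / tau
  J[cbind((n + 1):(2 * n), (n + 1):(2 * n))] <- -1 / tau
  attr(J, "n") <- n
  attr(J, "fixed_point") <- fp
  J
}

#' Eigen-analysis of the network Jacobian
#'
#' Full eigen-decomposition, eigenvalues sorted by descending real part. The
#' leading (maximal) eigenvector is the one paired with the largest real-part
#' eigenvalue; for a complex pair either member may be returned, which is
#' immaterial because node scores use the modulus. Node scores are the moduli
#' of the x-block components of the unit-norm maximal eigenvector: the
#' z-components are suppressed by O(1/tau) and the fast variable carries the
#' instability.
#'
#' @param J a Jacobian from [build_jacobian()] (or any square matrix with an
#'   even dimension 2N).
#' @param eps_pos tolerance distinguishing genuinely positive real parts from
#'   round-off (default 1e-8).
#' @return object of class `stability_report`: `eigenvalues` (complex, sorted
#'   by descending real part), `n_positive`, `max_eigenvector` (unit norm,
#'   length 2N), `node_scores` (length N), `n`.
#' @export
eigen_analysis <- function(J, eps_pos = 1e-8) {
  stopifnot(is.matrix(J), nrow(J) == ncol(J), nrow(J) %% 2 == 0)
  n <- nrow(J) / 2
  e <- tryCatch(eigen(J), error = function(err)
    stop(sprintf("eigen-decomposition failed: %s", conditionMessage(err)),
         call. = FALSE))
  ord <- order(-Re(e$values))
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  v <- vectors[, 1]
  v <- v / sqrt(sum(Mod(v)^2))
  structure(list(eigenvalues = values,
                 n_positive = sum(Re(values) > eps_pos),
                 max_eigenvector = v,
                 node_scores = Mod(v[seq_len(n)]),
                 n = as.integer(n)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("stability report: %d nodes, %d positive eigenvalue(s), max Re = %.4g\n",
              x$n, x$n_positive, Re(x$eigenvalues[1])))
  invisible(x)
}

#' Predict the propagation zone from the maximal eigenvector
#'
#' Non-EZ nodes whose x-block eigenvector modulus is "considerably large":
#' at least `eps_loc` in absolute mode (default 1e-5 on the unit-norm
#' eigenvector), or at least `eps_loc` times the largest non-EZ score in
#' relative mode. Returned sorted by descending score.
#'
#' @param report a [eigen_analysis()] result.
#' @param ez EZ node indices (excluded from the prediction).
#' @param eps_loc localization threshold.
#' @param mode `"absolute"` (default) or `"relative"`.
#' @return integer vector of predicted PZ nodes sorted by descending score,
#'   with attribute `score`.
#' @export
predict_pz <- function(report, ez, eps_loc = 1e-5,
                       mode = c("absolute", "relative")) {
  stopifnot(inherits(report, "stability_report"))
  mode <- match.arg(mode)
  scores <- report$node_scores
  cand <- setdiff(seq_len(report$n), ez)
  if (length(cand) == 0) return(structure(integer(0), score = numeric(0)))
  thr <- if (mode == "absolute") eps_loc else eps_loc * max(scores[cand])
  sel <- cand[scores[cand] >= thr]
  sel <- sel[order(-scores[sel], sel)]
  structure(as.integer(sel), score = scores[sel])
}

#' Maximum Lyapunov exponent and localization vector
#'
#' Integrates the tangent dynamics along the trajectory, renormalizing the
#' tangent vector periodically; the exponent is the average log growth rate
#' and the localization profile is the time-averaged modulus of the normalized
#' tangent vector's x-block, per node. For a system resting at a stable fixed
#' point this reproduces the largest Jacobian eigenvalue's real part; during
#' seizure propagation the profile localizes on the recruited pathways.
#'
#' @param c a `connectome`.
#' @param ex an [excitability_map()].
#' @param params a [model_params()].
#' @param horizon integration time.
#' @param renorm_interval renormalization interval (model time units).
#' @param init initial state as in [simulate_epileptor()].
#' @param rtol,atol,h_max integrator controls.
#' @param x0_healthy_ref healthy reference excitability for the default
#'   initial condition.
#' @return list with `exponent` (1/time units) and `profile` (length N,
#'   sums to 1).
#' @export
max_lyapunov <- function(c, ex, params = model_params(), horizon = 10000,
                         renorm_interval = 50, init = "fixed_point",
                         rtol = 1e-8, atol = 1e-10, h_max = 25,
                         x0_healthy_ref = -2.2) {
  stopifnot(inherits(c, "connectome"), inherits(ex, "excitability_map"))
  K <- c$weights
  n <- nrow(K)
  if (identical(init, "fixed_point")) {
    hp <- uncoupled_fixed_point(pmin(ex$x0, x0_healthy_ref), params)
    y0 <- c(hp$x_bar, hp$z_bar)
  } else {
    y0 <- as.numeric(init)
    if (length(y0) != 2 * n) stop("init state must have length 2N", call. = FALSE)
  }
  v0 <- rep(1, 2 * n)  # fixed deterministic tangent seed
  res <- cpp_lyapunov(K, ex$x0, params$tau, params$I_ext, y0, v0, horizon,
                      renorm_interval, rtol, atol, h_max)
  list(exponent = res$exponent, profile = as.numeric(res$profile),
       n_renorm = res$n_renorm)
}
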