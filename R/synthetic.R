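#' Parameters for the modular synthetic-connectome generator
#'
#' The generator emulates the statistical structure of normalized DTI
#' track-count matrices: symmetric non-negative weights, zero diagonal,
#' heavy-tailed (lognormal) weight distribution, max-normalized to 1, with
#' optional modular block structure.
#'
#' @param n_nodes number of regions (>= 2).
#' @param n_modules number of modules (>= 1).
#' @param p_within,p_between edge probabilities inside / between modules,
#'   `0 <= p_between <= p_within <= 1`.
#' @param weight_log_mean,weight_log_sd lognormal parameters of the nonzero
#'   weights (before max-normalization).
#' @param seed integer seed; identical seeds give bit-identical matrices.
#' @return object of class `synth_params`.
#' @export
synth_params <- function(n_nodes = 30, n_modules = 3, p_within = 0.8,
                         p_between = 0.05, weight_log_mean = 0,
                         weight_log_sd = 1, seed = 1) {
  if (n_nodes < 2) stop("n_nodes must be >= 2", call. = FALSE)
  if (n_modules < 1) stop("n_modules must be >= 1", call. = FALSE)
  if (n_modules > n_nodes) stop("n_modules must be <= n_nodes", call. = FALSE)
  if (!(p_between >= 0 && p_between <= p_within && p_within <= 1))
    stop("need 0 <= p_between <= p_within <= 1", call. = FALSE)
  if (weight_log_sd < 0) stop("weight_log_sd must be >= 0", call. = FALSE)
  structure(list(n_nodes = as.integer(n_nodes), n_modules = as.integer(n_modules),
                 p_within = p_within, p_between = p_between,
                 weight_log_mean = weight_log_mean, weight_log_sd = weight_log_sd,
                 seed = as.integer(seed)),
            class = "synth_params")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a modular synthetic connectome
#'
#' @param params a [synth_params()] object.
#' @return a normalized `connectome`; deterministic in `params$seed`.
#' @export
generate_modular <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  n <- params$n_nodes
  with_seed(params$seed, {
    module <- rep(seq_len(params$n_modules), length.out = n)
    module <- sort(module)
    w <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        p <- if (module[i] == module[j]) params$p_within else params$p_between
        if (stats::runif(1) < p) {
          w[i, j] <- w[j, i] <- stats::rlnorm(1, params$weight_log_mean,
                                              params$weight_log_sd)
        }
      }
    }
    if (max(w) == 0)
      stop("generated an all-zero network; increase edge probabilities", call. = FALSE)
    cn <- normalize_connectome(connectome(w))
    attr(cn, "module") <- module
    cn
  })
}

# Weak-weight ceiling for planted scenarios (on the strong-link ~ 1 scale).
# Calibrated so that background links can never transmit recruitment under the
# default dynamics: a healthy node (x0 = -2.2) destabilizes only when its
# summed seizing input exceeds ~0.38 in effective-excitability terms, while at
# most a handful of neighbours seize at once, bounding the worst-case shift by
# ~0.05 with this ceiling.
PLANTED_WEAK_MAX <- 0.02

#' Generate a planted-propagation scenario
#'
#' Builds a synthetic connectome with one epileptogenic node that has exactly
#' `n_strong` strong links (weights near 1) to designated propagation-zone
#' nodes, and only weak background links elsewhere (at most
#' `0.02` on the strong-link scale, so recruitment can only pass
#' through the planted links). This provides an unambiguous ground truth for
#' testing propagation-zone prediction and lesion planning.
#'
#' @param n_nodes number of regions (>= 4).
#' @param n_strong number of planted strong links, `1 <= n_strong <= n_nodes - 2`.
#' @param seed integer seed.
#' @param p_background background edge probability among non-EZ nodes.
#' @return object of class `planted_scenario`: list with `connectome`, `ez`
#'   (single node index), `planted_pz` (node indices), `planted_edges`
#'   (two-column matrix of (ez, pz) pairs), `seed`.
#' @export
generate_planted <- function(n_nodes = 30, n_strong = 3, seed = 1,
                             p_background = 0.3) {
  if (n_nodes < 4) stop("n_nodes must be >= 4", call. = FALSE)
  if (n_strong < 1 || n_strong > n_nodes - 2)
    stop(sprintf("n_strong must be in 1..%d", n_nodes - 2), call. = FALSE)
  with_seed(seed, {
    n <- n_nodes
    ez <- sample.int(n, 1)
    pz <- sample(setdiff(seq_len(n), ez), n_strong)
    w <- matrix(0, n, n)
    # weak heavy-ish background among all pairs, ceiling PLANTED_WEAK_MAX
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (stats::runif(1) < p_background) {
          w[i, j] <- w[j, i] <- stats::runif(1, 0.1, 1) * PLANTED_WEAK_MAX
        }
      }
    }
    # planted strong links, distinct weights near 1 so the eigenvector ranking
    # is well defined
    strong_w <- seq(1.0, 0.85, length.out = n_strong)
    for (k in seq_len(n_strong)) {
      w[ez, pz[k]] <- w[pz[k], ez] <- strong_w[k]
    }
    cn <- normalize_connectome(connectome(w))
    structure(list(connectome = cn, ez = ez, planted_pz = sort(pz),
                   planted_edges = cbind(ez = rep(ez, n_strong), pz = pz),
                   planted_weights = strong_w, seed = as.integer(seed)),
              class = "planted_scenario")
  })
}

#' @export
print.planted_scenario <- function(x, ...) {
  cat(sprintf("planted scenario: %d nodes, EZ = %d, planted PZ = {%s} (seed %d)\n",
              n_regions(x$connectome), x$ez,
              paste(x$planted_pz, collapse = ", "), x$seed))
  invisible(x)
}
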