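#' Containment test by simulation
#'
#' A lesioned network contains the seizure iff no non-EZ node is ever
#' recruited over the horizon: the EZ may still seize "asymptomatically".
#' Containment is decided by simulation rather than by the eigenspectrum
#' because the EZ's own instability keeps positive eigenvalues in the spectrum
#' even after a successful disconnection.
#'
#' @param c a `connectome`.
#' @param ex an [excitability_map()].
#' @param params a [model_params()].
#' @param horizon simulated duration (default `10 * tau`).
#' @param theta_on,theta_off,min_duration event-detection thresholds, see
#'   [detect_seizure_events()].
#' @param dt_out output sampling step for the raster.
#' @param early_stop terminate the simulation at the first recruitment
#'   (default `TRUE`; the verdict is identical, the raster is truncated).
#' @param ... further arguments passed to [simulate_epileptor()].
#' @return list with `contained` (logical) and `raster` (a `seizure_raster`).
#' @export
containment_test <- function(c, ex, params = model_params(),
                             horizon = 10 * params$tau, theta_on = 0,
                             theta_off = -1, min_duration = 5, dt_out = 5,
                             early_stop = TRUE, ...) {
  stopifnot(inherits(c, "connectome"), inherits(ex, "excitability_map"))
  n <- n_regions(c)
  watch <- if (early_stop) setdiff(seq_len(n), ex$ez) else integer(0)
  traj <- simulate_epileptor(c, ex, params, horizon = horizon, dt_out = dt_out,
                             watch = watch, theta_watch = theta_on, ...)
  raster <- detect_seizure_events(traj, theta_on, theta_off, min_duration)
  contained <- if (traj$stopped) FALSE
               else length(recruited_set(raster, ex$ez)) == 0
  list(contained = contained, raster = raster)
}

lesion_strategies <- c("full_disconnection", "random", "strongest_macroarea",
                       "strongest_ez", "lsa")

new_lesion_plan <- function(strategy, removed, per_step, contained, capped,
                            extra = list()) {
  removed_df <- if (length(removed) > 0) {
    do.call(rbind, lapply(removed, function(r)
      data.frame(i = r[1], j = r[2], weight = r[3])))
  } else data.frame(i = integer(0), j = integer(0), weight = numeric(0))
  per_step_df <- if (length(per_step) > 0) {
    do.call(rbind, lapply(per_step, function(r)
      data.frame(n_positive = r[1], pz_size = r[2])))
  } else data.frame(n_positive = integer(0), pz_size = integer(0))
  structure(c(list(strategy = strategy, removed_edges = removed_df,
                   n_lesions = nrow(removed_df), per_step = per_step_df,
                   contained = contained, capped = capped), extra),
            class = "lesion_plan")
}

#' @export
print.lesion_plan <- function(x, ...) {
  cat(sprintf("lesion plan [%s]: %s lesion(s), %s%s\n", x$strategy,
              format(x$n_lesions), if (isTRUE(x$contained)) "contained"
                                   else "NOT contained",
              if (isTRUE(x$capped)) " (cap reached)" else ""))
  invisible(x)
}

# n_positive and predicted-PZ size of a (possibly lesioned) connectome
spectral_step <- function(c, ex, params, eps_loc, eps_pos = 1e-8) {
  fp <- network_fixed_point(c, ex, params)
  if (!fp$converged)
    stop("fixed-point solver did not converge during lesion planning", call. = FALSE)
  report <- eigen_analysis(build_jacobian(c, fp, params), eps_pos)
  pz <- predict_pz(report, ex$ez, eps_loc)
  list(report = report, pz = pz)
}

#' Plan lesions under a named strategy
#'
#' Five strategies are implemented. `full_disconnection` removes every
#' positive-weight edge incident to the EZ at once (the standard-resection
#' analogue). `random` removes seeded random EZ-incident edges one at a time
#' until containment, averaged over `replicates` realizations.
#' `strongest_ez` removes EZ-incident edges in order of descending weight
#' until containment. `strongest_macroarea` does the same for edges incident
#' to the EZ + predicted-PZ macro-area (PZ from the unlesioned system; the
#' larger candidate pool makes it less targeted than `strongest_ez`). `lsa`
#' iterates the linear-stability loop: fixed point, Jacobian, maximal
#' eigenvector; cuts the strongest link between the EZ and the
#' highest-scoring non-EZ node still connected to it; re-checks containment
#' whenever the predicted PZ is empty (and every `check_every` cuts).
#'
#' Ties are always broken towards smaller node indices, and random replicate
#' seeds are derived from the master seed, so plans are reproducible.
#'
#' @param c a `connectome`.
#' @param ex an [excitability_map()] with non-empty EZ (except for isolated
#'   EZ nodes, which are trivially contained).
#' @param params a [model_params()].
#' @param strategy one of `"full_disconnection"`, `"random"`,
#'   `"strongest_macroarea"`, `"strongest_ez"`, `"lsa"`.
#' @param max_lesions cap on the number of removals per plan (default 20).
#' @param seed master seed for the `random` strategy.
#' @param replicates number of random realizations (default 5).
#' @param horizon containment-test horizon.
#' @param eps_loc eigenvector localization threshold for [predict_pz()].
#' @param check_every for `lsa`: containment is also tested every this many
#'   cuts even while the predicted PZ is non-empty.
#' @param ... further arguments passed to [containment_test()].
#' @return a `lesion_plan`; for `random`, `n_lesions` is the mean over
#'   replicates and `$replicates` holds the per-replicate plans. If the
#'   candidate set is exhausted before containment the plan is returned with
#'   `contained = FALSE` and `capped = TRUE`.
#' @export
plan_lesions <- function(c, ex, params = model_params(),
                         strategy = lesion_strategies, max_lesions = 20,
                         seed = 1, replicates = 5,
                         horizon = 10 * params$tau, eps_loc = 1e-5,
                         check_every = 5, ...) {
  stopifnot(inherits(c, "connectome"), inherits(ex, "excitability_map"))
  strategy <- match.arg(strategy)
  if (length(ex$ez) == 0) stop("EZ is empty", call. = FALSE)
  contain <- function(cn) containment_test(cn, ex, params, horizon = horizon, ...)$contained

  if (strategy == "full_disconnection") {
    cand <- incident_edges(c, ex$ez)
    cn <- c
    removed <- list()
    for (r in seq_len(nrow(cand))) {
      cn <- remove_edge(cn, cand$i[r], cand$j[r])
      removed[[r]] <- c(cand$i[r], cand$j[r], cand$weight[r])
    }
    st <- spectral_step(cn, ex, params, eps_loc)
    return(new_lesion_plan(strategy, removed,
                           list(c(st$report$n_positive, length(st$pz))),
                           contained = contain(cn), capped = FALSE))
  }

  if (strategy == "random") {
    seeds <- with_seed(seed, sample.int(.Machine$integer.max, replicates))
    reps <- lapply(seq_len(replicates), function(r) {
      cand <- incident_edges(c, ex$ez)
      ord <- with_seed(seeds[r], sample.int(nrow(cand)))
      cand <- cand[ord, , drop = FALSE]
      sequential_removal(c, ex, params, cand, max_lesions = nrow(cand),
                         contain = contain, eps_loc = eps_loc,
                         strategy = "random", track_spectrum = FALSE)
    })
    counts <- vapply(reps, `[[`, 0, "n_lesions")
    plan <- new_lesion_plan("random", list(), list(),
                            contained = all(vapply(reps, `[[`, TRUE, "contained")),
                            capped = any(vapply(reps, function(p) isTRUE(p$capped), TRUE)),
                            extra = list(replicates = reps, seed = seed,
                                         replicate_seeds = seeds))
    plan$removed_edges <- reps[[1]]$removed_edges
    plan$n_lesions <- mean(counts)
    plan$per_step <- reps[[1]]$per_step
    return(plan)
  }

  if (strategy == "strongest_ez") {
    cand <- incident_edges(c, ex$ez)
    return(sequential_removal(c, ex, params, cand, max_lesions, contain,
                              eps_loc, strategy))
  }

  if (strategy == "strongest_macroarea") {
    st0 <- spectral_step(c, ex, params, eps_loc)
    macro <- union(ex$ez, st0$pz)
    cand <- incident_edges(c, macro)
    return(sequential_removal(c, ex, params, cand, max_lesions, contain,
                              eps_loc, strategy))
  }

  # lsa
  cn <- c
  removed <- list()
  per_step <- list()
  steps <- 0L
  contained <- NA
  capped <- FALSE
  repeat {
    st <- spectral_step(cn, ex, params, eps_loc)
    if (steps > 0)
      per_step[[steps]] <- c(st$report$n_positive, length(st$pz))
    if (length(st$pz) == 0 || (steps > 0 && steps %% check_every == 0)) {
      if (contain(cn)) { contained <- TRUE; break }
    }
    if (steps >= max_lesions) {
      contained <- contain(cn)
      capped <- !contained
      break
    }
    # target: highest-scoring non-EZ node still linked to the EZ
    scores <- st$report$node_scores
    linked <- which(colSums(cn$weights[ex$ez, , drop = FALSE] > 0) > 0)
    targets <- setdiff(linked, ex$ez)
    if (length(targets) == 0) {
      contained <- contain(cn)
      capped <- !contained
      break
    }
    tgt <- targets[order(-scores[targets], targets)][1]
    wts <- cn$weights[ex$ez, tgt]
    e <- ex$ez[order(-wts, ex$ez)][1]
    removed[[steps + 1L]] <- c(e, tgt, cn$weights[e, tgt])
    cn <- remove_edge(cn, e, tgt)
    steps <- steps + 1L
  }
  new_lesion_plan("lsa", removed, per_step, contained, capped)
}

# Remove candidate edges in the given order, testing containment after each
# removal; stops at containment, candidate exhaustion, or the cap.
sequential_removal <- function(c, ex, params, cand, max_lesions, contain,
                               eps_loc, strategy, track_spectrum = TRUE) {
  cn <- c
  removed <- list()
  per_step <- list()
  contained <- contain(cn)
  capped <- FALSE
  r <- 0L
  while (!contained) {
    if (r >= nrow(cand) || r >= max_lesions) {
      capped <- TRUE
      break
    }
    r <- r + 1L
    removed[[r]] <- c(cand$i[r], cand$j[r], cn$weights[cand$i[r], cand$j[r]])
    cn <- remove_edge(cn, cand$i[r], cand$j[r])
    if (track_spectrum) {
      st <- spectral_step(cn, ex, params, eps_loc)
      per_step[[r]] <- c(st$report$n_positive, length(st$pz))
    }
    contained <- contain(cn)
  }
  new_lesion_plan(strategy, removed, per_step, contained, capped)
}

#' Replay a lesion plan on a fresh connectome
#'
#' @param c a `connectome`.
#' @param plan a `lesion_plan`.
#' @return the lesioned `connectome`.
#' @export
apply_lesion_plan <- function(c, plan) {
  stopifnot(inherits(c, "connectome"), inherits(plan, "lesion_plan"))
  e <- plan$removed_edges
  for (r in seq_len(nrow(e))) c <- remove_edge(c, e$i[r], e$j[r])
  c
}

#' Compare lesioning strategies on one network
#'
#' @param c a `connectome`.
#' @param ex an [excitability_map()].
#' @param params a [model_params()].
#' @param strategies strategy names (default: all five).
#' @param seed master seed (drives the `random` strategy).
#' @param ... passed to [plan_lesions()].
#' @return data.frame with one row per strategy: `strategy`, `n_lesions`
#'   (mean over replicates for `random`), `contained`; attribute `plans`
#'   holds the full plans. Deterministic given `seed`.
#' @export
compare_strategies <- function(c, ex, params = model_params(),
                               strategies = lesion_strategies, seed = 1, ...) {
  if (length(strategies) < 1) stop("need at least one strategy", call. = FALSE)
  strategies <- match.arg(strategies, lesion_strategies, several.ok = TRUE)
  plans <- lapply(strategies, function(s)
    plan_lesions(c, ex, params, strategy = s, seed = seed, ...))
  out <- data.frame(strategy = strategies,
                    n_lesions = vapply(plans, `[[`, 0, "n_lesions"),
                    contained = vapply(plans, function(p) isTRUE(p$contained), TRUE))
  attr(out, "plans") <- stats::setNames(plans, strategies)
  out
}
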