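#' Sweep the epileptogenic zone over every node
#'
#' For each node in turn, places a single-node EZ there, runs
#' [plan_lesions()] under the chosen strategy, and records the number of
#' lesions needed to stop propagation together with the predicted-PZ size
#' after each lesion step. Per-node failures are recorded and the sweep
#' continues; results are independent of sweep order.
#'
#' @param c a `connectome`.
#' @param params a [model_params()].
#' @param x0_ez,x0_healthy two-level excitability assignment for each sweep
#'   position.
#' @param strategy lesioning strategy (default `"lsa"`).
#' @param max_lesions cap per node (default 20); capped nodes are flagged and
#'   excluded from downstream correlations.
#' @param nodes subset of candidate EZ nodes (default: all).
#' @param ... further arguments passed to [plan_lesions()].
#' @return object of class `sweep_result`: `lesions_needed` (length-N vector,
#'   `NA` for failed nodes), `pz_size_map` (N x max_lesions matrix, entry
#'   `[i, s]` = predicted-PZ size after lesion `s` with the EZ at node `i`,
#'   `NA` beyond the plan length), `capped`, `failed`, `nodes`.
#' @export
ez_sweep <- function(c, params = model_params(), x0_ez = -1.6,
                     x0_healthy = -2.2, strategy = "lsa", max_lesions = 20,
                     nodes = seq_len(n_regions(c)), ...) {
  stopifnot(inherits(c, "connectome"))
  n <- n_regions(c)
  lesions_needed <- rep(NA_real_, n)
  capped <- rep(FALSE, n)
  failed <- rep(FALSE, n)
  pz_size_map <- matrix(NA_real_, n, max_lesions)
  for (i in nodes) {
    ex <- excitability_from_ez(n, ez = i, x0_ez = x0_ez,
                               x0_healthy = x0_healthy, params = params)
    plan <- tryCatch(
      plan_lesions(c, ex, params, strategy = strategy,
                   max_lesions = max_lesions, ...),
      error = function(e) e)
    if (inherits(plan, "error")) {
      failed[i] <- TRUE
      next
    }
    lesions_needed[i] <- plan$n_lesions
    capped[i] <- isTRUE(plan$capped)
    ns <- nrow(plan$per_step)
    if (ns > 0)
      pz_size_map[i, seq_len(min(ns, max_lesions))] <-
        plan$per_step$pz_size[seq_len(min(ns, max_lesions))]
  }
  structure(list(lesions_needed = lesions_needed, pz_size_map = pz_size_map,
                 capped = capped, failed = failed, nodes = nodes,
                 strategy = strategy, max_lesions = max_lesions),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  ok <- x$nodes[!x$failed[x$nodes]]
  cat(sprintf("EZ sweep [%s]: %d nodes, lesions needed %g-%g (median %g), %d capped, %d failed\n",
              x$strategy, length(x$nodes),
              min(x$lesions_needed[ok], na.rm = TRUE),
              max(x$lesions_needed[ok], na.rm = TRUE),
              stats::median(x$lesions_needed[ok], na.rm = TRUE),
              sum(x$capped), sum(x$failed)))
  invisible(x)
}

#' Correlate lesions-needed with nodal graph metrics
#'
#' Pearson correlation (with the two-sided t-test p-value) between the number
#' of lesions needed when the EZ sits at a node and each nodal metric of that
#' node. Capped and failed nodes are excluded. Zero-variance metrics yield
#' `NA` correlations (reported, not an error).
#'
#' @param sweep a [ez_sweep()] result.
#' @param metrics a [nodal_metrics()] table for the same connectome.
#' @return data.frame with columns `metric`, `r`, `p`, `n_used`.
#' @export
metric_lesion_correlation <- function(sweep, metrics) {
  stopifnot(inherits(sweep, "sweep_result"), is.data.frame(metrics))
  if (nrow(metrics) != length(sweep$lesions_needed))
    stop("metrics table does not match sweep size", call. = FALSE)
  use <- intersect(sweep$nodes,
                   which(!sweep$capped & !sweep$failed &
                         !is.na(sweep$lesions_needed)))
  if (length(use) < 3)
    stop("need at least 3 uncapped nodes for correlation", call. = FALSE)
  y <- sweep$lesions_needed[use]
  metric_names <- c("degree", "strength", "clustering", "efficiency",
                    "betweenness", "closeness")
  rows <- lapply(metric_names, function(m) {
    v <- metrics[[m]][use]
    if (stats::sd(v) == 0 || stats::sd(y) == 0)
      return(data.frame(metric = m, r = NA_real_, p = NA_real_,
                        n_used = length(use)))
    ct <- stats::cor.test(v, y, method = "pearson")
    data.frame(metric = m, r = unname(ct$estimate), p = ct$p.value,
               n_used = length(use))
  })
  do.call(rbind, rows)
}
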