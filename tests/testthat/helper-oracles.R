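# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the vector field and Jacobian are re-derived in
# plain R, graph measures by exhaustive path enumeration.

# Direct R translation of the coupled Epileptor vector field.
oracle_field <- function(K, x0, tau, I) {
  n <- length(x0)
  s <- rowSums(K)
  function(y) {
    x <- y[1:n]
    z <- y[(n + 1):(2 * n)]
    c(-x^3 - 2 * x^2 + 1 - z + I,
      (4 * (x - x0) - z - (as.vector(K %*% x) - s * x)) / tau)
  }
}

# Central finite differences of a vector field.
fd_jacobian <- function(f, y, h = 1e-6) {
  m <- length(y)
  J <- matrix(0, m, m)
  for (k in seq_len(m)) {
    yp <- y; ym <- y
    yp[k] <- yp[k] + h
    ym[k] <- ym[k] - h
    J[, k] <- (f(yp) - f(ym)) / (2 * h)
  }
  J
}

# Closed-form spectrum of one uncoupled node's 2x2 Jacobian block.
node_spectrum_closed <- function(xbar, tau = 2857) {
  a <- -3 * xbar^2 - 4 * xbar
  tr <- a - 1 / tau
  det <- (4 - a) / tau
  sq <- sqrt(as.complex(tr^2 - 4 * det))
  c((tr + sq) / 2, (tr - sq) / 2)
}

# Exhaustive-path graph oracle (feasible for N <= 7): distances via full
# simple-path enumeration with d = 1/weight, betweenness with fractional
# credit, nodal efficiency/closeness, binary clustering by triangle counting.
brute_graph_oracle <- function(w) {
  n <- nrow(w)
  all_paths <- function(s, t) {
    res <- list()
    dfs <- function(v, visited, dist) {
      if (v == t) {
        res[[length(res) + 1]] <<- list(dist = dist, nodes = visited)
        return(invisible())
      }
      for (u in which(w[v, ] > 0)) {
        if (!(u %in% visited)) dfs(u, c(visited, u), dist + 1 / w[v, u])
      }
    }
    dfs(s, s, 0)
    res
  }
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  bw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      ps <- all_paths(s, t)
      if (length(ps) == 0) next
      dists <- vapply(ps, `[[`, 0, "dist")
      dmin <- min(dists)
      d[s, t] <- d[t, s] <- dmin
      sp <- ps[dists - dmin < 1e-9]
      for (v in setdiff(seq_len(n), c(s, t))) {
        cnt <- sum(vapply(sp, function(pp) v %in% pp$nodes, TRUE))
        bw[v] <- bw[v] + cnt / length(sp)
      }
    }
  }
  eff <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    mean(ifelse(is.finite(di), 1 / di, 0))
  }, 0.0)
  clo <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (length(di) == 0 || sum(di) == 0) 0 else length(di) / sum(di)
  }, 0.0)
  clu <- vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    pairs <- utils::combn(nb, 2)
    mean(w[t(pairs)] > 0)
  }, 0.0)
  list(d = d, betweenness = bw / ((n - 1) * (n - 2) / 2),
       efficiency = eff, closeness = clo, clustering = clu)
}

# Canonical string keys for undirected edge sets.
edge_keys <- function(i, j) sort(paste(pmin(i, j), pmax(i, j), sep = "-"))

# Small hand-built connectome: EZ-style hub 1 strongly tied to 2, weak elsewhere.
toy_connectome <- function() {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  w[3, 4] <- w[4, 3] <- 0.01
  w[2, 3] <- w[3, 2] <- 0.01
  connectome(w)
}

# Fake trajectory wrapper for event-detection tests.
fake_trajectory <- function(times, x) {
  structure(list(times = times, x = x, z = matrix(0, nrow(x), ncol(x)),
                 stopped = FALSE, t_stop = NA_real_, horizon = max(times),
                 labels = default_labels_n(ncol(x))),
            class = "epi_trajectory")
}
default_labels_n <- function(n) sprintf("R%03d", seq_len(n))
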