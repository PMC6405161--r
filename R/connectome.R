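#' Construct a structural connectome
#'
#' A connectome is a square, symmetric, non-negative weight matrix with zero
#' diagonal, typically derived from diffusion tractography track counts, plus
#' one label per region. Matrices that are asymmetric beyond `1e-12` are
#' symmetrized as \eqn{(K + K^T)/2} with a warning, since tractography-derived
#' connectivity is undirected.
#'
#' @param weights square numeric matrix of non-negative, finite weights with
#'   zero diagonal.
#' @param labels optional character vector of region names, one per row;
#'   defaults to `"R001" ... "R{N}"`.
#' @param normalized optional logical; if `NULL`, inferred as `TRUE` when the
#'   maximum entry equals 1.
#' @return An object of class `connectome`: a list with elements `weights`,
#'   `labels`, `normalized`.
#' @examples
#' w <- matrix(c(0, 1, 0.5, 1, 0, 0, 0.5, 0, 0), 3, 3)
#' connectome(w)
#' @export
connectome <- function(weights, labels = NULL, normalized = NULL) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("weights must be a numeric matrix", call. = FALSE)
  n <- nrow(weights)
  if (ncol(weights) != n)
    stop(sprintf("non-square matrix: %d rows but %d columns", n, ncol(weights)),
         call. = FALSE)
  bad <- which(!is.finite(weights))
  if (length(bad) > 0) {
    ij <- arrayInd(bad[1], dim(weights))
    stop(sprintf("non-finite entry at [%d, %d]", ij[1], ij[2]), call. = FALSE)
  }
  bad <- which(weights < 0)
  if (length(bad) > 0) {
    ij <- arrayInd(bad[1], dim(weights))
    stop(sprintf("negative entry %g at [%d, %d]", weights[bad[1]], ij[1], ij[2]),
         call. = FALSE)
  }
  if (any(diag(weights) != 0)) {
    i <- which(diag(weights) != 0)[1]
    stop(sprintf("nonzero diagonal entry %g at [%d, %d] (self-connections are not allowed)",
                 diag(weights)[i], i, i), call. = FALSE)
  }
  asym <- max(abs(weights - t(weights)))
  if (asym > 1e-12) {
    warning(sprintf("matrix asymmetric (max |K - t(K)| = %g); symmetrizing as (K + t(K))/2",
                    asym), call. = FALSE)
    weights <- (weights + t(weights)) / 2
  } else if (asym > 0) {
    weights <- (weights + t(weights)) / 2
  }
  if (is.null(labels)) {
    labels <- default_labels(n)
  } else {
    labels <- as.character(labels)
    if (length(labels) != n)
      stop(sprintf("label count (%d) does not match matrix size (%d)",
                   length(labels), n), call. = FALSE)
  }
  if (is.null(normalized)) normalized <- (max(weights) == 1)
  dimnames(weights) <- NULL
  structure(list(weights = weights, labels = labels,
                 normalized = isTRUE(normalized)),
            class = "connectome")
}

default_labels <- function(n) sprintf("R%03d", seq_len(n))

#' Number of regions in a connectome
#' @param c a `connectome`.
#' @return integer node count N.
#' @export
n_regions <- function(c) nrow(c$weights)

#' @export
print.connectome <- function(x, ...) {
  w <- x$weights
  nz <- sum(w[upper.tri(w)] > 0)
  cat(sprintf("connectome: %d regions, %d edges, max weight %g%s\n",
              nrow(w), nz, max(w), if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Read a connectome from a delimited text file
#'
#' Accepts a comma- or whitespace-delimited square numeric matrix, one row per
#' line, with an optional label sidecar file (one region name per line, same
#' order as the matrix rows).
#'
#' @param path path to the matrix file.
#' @param labels_path optional path to the label sidecar.
#' @return a validated [connectome()].
#' @export
read_connectome <- function(path, labels_path = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  m <- tryCatch(
    as.matrix(utils::read.table(path, sep = sep, header = FALSE,
                                colClasses = "numeric", comment.char = "#")),
    error = function(e) stop(sprintf("cannot parse %s as a numeric matrix: %s",
                                     path, conditionMessage(e)), call. = FALSE))
  labels <- NULL
  if (!is.null(labels_path)) {
    if (!file.exists(labels_path))
      stop(sprintf("file not found: %s", labels_path), call. = FALSE)
    labels <- trimws(readLines(labels_path))
    labels <- labels[nzchar(labels)]
  }
  connectome(m, labels = labels)
}

#' Write a connectome to delimited text
#'
#' Emits full precision (round-trip through [read_connectome()] is exact).
#'
#' @param c a `connectome`.
#' @param path output matrix path.
#' @param labels_path optional output path for the label sidecar.
#' @param sep field separator, `","` (default) or whitespace.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(c, path, labels_path = NULL, sep = ",") {
  stopifnot(inherits(c, "connectome"))
  rows <- apply(c$weights, 1, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = sep))
  writeLines(rows, path)
  if (!is.null(labels_path)) writeLines(c$labels, labels_path)
  invisible(path)
}

#' Rescale a connectome so that its maximum weight is 1
#'
#' Division of every entry by the maximum entry; idempotent.
#'
#' @param c a `connectome` with at least one positive weight.
#' @return the normalized `connectome`.
#' @export
normalize_connectome <- function(c) {
  stopifnot(inherits(c, "connectome"))
  mx <- max(c$weights)
  if (mx == 0) stop("cannot normalize an all-zero matrix", call. = FALSE)
  if (mx == 1) {
    c$normalized <- TRUE
    return(c)
  }
  connectome(c$weights / mx, labels = c$labels, normalized = TRUE)
}

#' Remove (zero) one edge of a connectome
#'
#' Virtual ablation of a single link: sets the symmetric weight pair
#' `(i, j)`, `(j, i)` to zero, leaving all other entries untouched. Idempotent.
#'
#' @param c a `connectome`.
#' @param i,j node indices (1-based), `i != j`.
#' @return a copy of `c` with the edge removed.
#' @export
remove_edge <- function(c, i, j) {
  stopifnot(inherits(c, "connectome"))
  n <- n_regions(c)
  i <- as.integer(i); j <- as.integer(j)
  if (length(i) != 1 || length(j) != 1 || is.na(i) || is.na(j) ||
      i < 1 || j < 1 || i > n || j > n)
    stop(sprintf("edge indices out of range 1..%d", n), call. = FALSE)
  if (i == j)
    stop(sprintf("cannot remove self-edge (%d, %d): self-connections do not exist", i, j),
         call. = FALSE)
  c$weights[i, j] <- 0
  c$weights[j, i] <- 0
  c$normalized <- (max(c$weights) == 1)
  c
}

#' Average several connectomes
#'
#' Element-wise arithmetic mean of same-sized connectomes, re-normalized to
#' maximum weight 1 afterwards so that downstream dynamics see the same
#' coupling scale as an individual matrix. Labels are taken from the first
#' input.
#'
#' @param cs non-empty list of `connectome` objects of equal size.
#' @return the average `connectome` (normalized).
#' @export
average_connectomes <- function(cs) {
  if (!is.list(cs) || length(cs) == 0)
    stop("need a non-empty list of connectomes", call. = FALSE)
  stopifnot(all(vapply(cs, inherits, TRUE, "connectome")))
  ns <- vapply(cs, n_regions, 0L)
  if (length(unique(ns)) != 1)
    stop(sprintf("size mismatch: connectomes have %s regions",
                 paste(unique(ns), collapse = ", ")), call. = FALSE)
  w <- Reduce(`+`, lapply(cs, `[[`, "weights")) / length(cs)
  normalize_connectome(connectome(w, labels = cs[[1]]$labels))
}

#' Edges incident to a node set
#'
#' @param c a `connectome`.
#' @param nodes node indices.
#' @param exclusive if `TRUE`, keep only edges with exactly one endpoint in
#'   `nodes` (edges leaving the set); if `FALSE`, any edge touching the set.
#' @return data.frame with columns `i`, `j` (`i < j`) and `weight`, positive
#'   weights only, sorted by descending weight with ties broken by smaller
#'   node indices.
#' @export
incident_edges <- function(c, nodes, exclusive = FALSE) {
  stopifnot(inherits(c, "connectome"))
  w <- c$weights
  n <- nrow(w)
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    in_i <- idx[, 1] %in% nodes
    in_j <- idx[, 2] %in% nodes
    keep <- if (exclusive) xor(in_i, in_j) else (in_i | in_j)
    idx <- idx[keep, , drop = FALSE]
  }
  df <- data.frame(i = idx[, 1], j = idx[, 2],
                   weight = w[idx, drop = FALSE])
  df <- df[order(-df$weight, df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  df
}
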