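#' Estimate the number of communities in a weighted network
#'
#' Fits the nDFAwm estimator: for each candidate `k = 1..K0`, the network
#' is clustered by nDFA spectral clustering ([ndfa()]) and the partition
#' is scored by the generalized weighted modularity
#' ([weighted_modularity()]); the estimated number of communities
#' `K_hat` is the `k` maximizing the modularity curve. The method applies
#' to any undirected network with finite real edge weights — nonnegative,
#' mixed-sign, or signed (`{-1, +1}`) — and also handles the
#' single-community case (`K_hat = 1`, where every modularity is 0 and the
#' smallest maximizer is reported).
#'
#' `K0` caps the search. The default `min(n, 20)` suits networks whose
#' community count is moderate; pass `K0 = nrow(A)` for a fully agnostic
#' (slower) search.
#'
#' @param A Symmetric numeric adjacency matrix (e.g. from
#'   [read_network()] or [sample_adjacency()]), or an `igraph` graph
#'   (converted via its `weight` edge attribute, weight 1 if absent).
#' @param K0 Largest candidate number of communities (default
#'   `min(n, 20)`).
#' @param restarts k-means restarts per candidate `k`.
#' @param seed Optional integer seed; the fit is deterministic given
#'   `(A, K0, restarts, seed)`.
#' @param ordering Eigenvalue ordering for the spectral step, see
#'   [top_k_eigen()].
#' @param early_stop Stop scanning `k` once the modularity stops
#'   increasing instead of scanning all of `1..K0`.
#' @return An object of class `"ndfawm"` with components `K_hat`,
#'   `Q_hat` (modularity at `K_hat`), `curve` (the
#'   [modularity_curve()]), `membership` (labels at `K_hat`), `n`, `K0`,
#'   and `call`. Methods: `print`, `summary`, `plot`, `coef` (returns
#'   `K_hat`), `labels` (returns the membership vector).
#' @examples
#' spec <- dcdfm_spec(40, 2, rep(1:2, 20), runif(40) * 0.9 + 0.05,
#'                    matrix(c(1, 0.1, 0.1, 0.9), 2), "poisson")
#' fit <- ndfawm(sample_adjacency(spec, seed = 3), seed = 1)
#' fit
#' coef(fit)
#' @export
ndfawm <- function(A, K0 = min(nrow(A), 20L), restarts = 10, seed = NULL,
                   ordering = c("magnitude", "algebraic"),
                   early_stop = FALSE) {
  cl <- match.call()
  if (inherits(A, "igraph")) A <- graph_to_adjacency(A)
  if (!is.matrix(A) || !is.numeric(A))
    stop("`A` must be a numeric matrix or an igraph graph", call. = FALSE)
  if (nrow(A) != ncol(A) || !isSymmetric(unname(A), tol = 1e-8))
    stop("`A` must be a symmetric adjacency matrix", call. = FALSE)
  ordering <- match.arg(ordering)
  curve <- modularity_curve(A, K0 = K0, restarts = restarts, seed = seed,
                            ordering = ordering, early_stop = early_stop)
  membership <- curve$labels[[curve$K_hat]]
  structure(
    list(K_hat = curve$K_hat, Q_hat = curve$Q[curve$K_hat], curve = curve,
         membership = as.integer(membership), n = nrow(A), K0 = K0,
         seed = seed, call = cl),
    class = "ndfawm")
}

#' @export
print.ndfawm <- function(x, ...) {
  cat("nDFAwm community-count estimate\n")
  cat(sprintf("  n = %d nodes, candidates k = 1..%d\n", x$n, x$K0))
  cat(sprintf("  K_hat = %d  (weighted modularity Q = %.4f)\n",
              x$K_hat, x$Q_hat))
  invisible(x)
}

#' @export
summary.ndfawm <- function(object, ...) {
  sizes <- tabulate(object$membership, object$K_hat)
  out <- list(K_hat = object$K_hat, Q_hat = object$Q_hat,
              sizes = sizes, n = object$n, K0 = object$K0,
              curve = data.frame(k = object$curve$k, Q = object$curve$Q),
              call = object$call)
  class(out) <- "summary.ndfawm"
  out
}

#' @export
print.summary.ndfawm <- function(x, ...) {
  cat("nDFAwm community-count estimate\n\nCall:\n  ")
  print(x$call)
  cat(sprintf("\nn = %d nodes scanned over k = 1..%d\n", x$n, x$K0))
  cat(sprintf("Estimated number of communities: K_hat = %d\n", x$K_hat))
  cat(sprintf("Weighted modularity at K_hat:    Q = %.4f\n", x$Q_hat))
  cat("Community sizes at K_hat: ", paste(x$sizes, collapse = ", "), "\n")
  cat("\nModularity curve (k, Q):\n")
  print(x$curve, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.ndfawm <- function(object, ...) {
  c(K_hat = object$K_hat)
}

#' @export
labels.ndfawm <- function(object, ...) {
  object$membership
}

#' Plot the weighted-modularity curve of a fitted nDFAwm estimate
#'
#' @param x A fitted `"ndfawm"` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ndfawm <- function(x, ...) {
  args <- list(x = x$curve$k, y = x$curve$Q, type = "b",
               xlab = "number of communities k",
               ylab = "weighted modularity Q", ...)
  if (is.null(args$main))
    args$main <- sprintf("nDFAwm: K_hat = %d", x$K_hat)
  do.call(graphics::plot, args)
  graphics::abline(v = x$K_hat, lty = 2, col = "grey40")
  invisible(x)
}

# igraph -> dense symmetric adjacency with weights (1 when unweighted)
graph_to_adjacency <- function(g) {
  attr_name <- if ("weight" %in% igraph::edge_attr_names(g)) "weight" else NULL
  M <- igraph::as_adjacency_matrix(g, type = "both", attr = attr_name,
                                   sparse = FALSE)
  unname(M)
}
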