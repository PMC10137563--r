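#' Split a weighted network into its positive and negative parts
#'
#' Decomposes a finite real adjacency matrix as `A = A_plus - A_minus`
#' with `A_plus = pmax(A, 0)` and `A_minus = pmax(-A, 0)`, together with
#' the positive/negative degree vectors `d_plus`, `d_minus` (row sums) and
#' total weights `m_plus = sum(d_plus) / 2`, `m_minus = sum(d_minus) / 2`.
#'
#' @param A Symmetric numeric matrix with finite entries.
#' @return A list of class `"sign_split"` with components `A_plus`,
#'   `A_minus`, `d_plus`, `d_minus`, `m_plus`, `m_minus`.
#' @examples
#' sign_split(matrix(c(0, -1, -1, 0), 2))$m_minus
#' @export
sign_split <- function(A) {
  if (any(!is.finite(A)))
    stop("adjacency matrix must have finite entries", call. = FALSE)
  Ap <- pmax(A, 0)
  Am <- pmax(-A, 0)
  dp <- rowSums(Ap)
  dm <- rowSums(Am)
  structure(list(A_plus = Ap, A_minus = Am, d_plus = dp, d_minus = dm,
                 m_plus = sum(dp) / 2, m_minus = sum(dm) / 2),
            class = "sign_split")
}

#' Generalized weighted modularity of a partition
#'
#' Scores a community partition of a network whose edge weights may be any
#' finite real values. Writing `A = A_plus - A_minus`, the positive and
#' negative modularities are
#' \deqn{Q^{\pm} = \frac{1}{2m^{\pm}} \sum_{i,j}
#'   \Big(A^{\pm}_{ij} - \frac{d^{\pm}_i d^{\pm}_j}{2m^{\pm}}\Big)
#'   \delta(\ell_i, \ell_j) \, 1\{m^{\pm} > 0\},}
#' (a modularity of 0 when the corresponding part is empty), and the
#' combined score is the convex combination
#' \deqn{Q = \frac{2m^+ Q^+ - 2m^- Q^-}{2m^+ + 2m^-}.}
#' With no negative weights this is exactly the Newman–Girvan modularity;
#' for a signed network it is the signed modularity of Gómez–Jensen–Arenas.
#' `Q` lies in `[-1, 1]`, equals 0 for the one-community partition, and a
#' larger value indicates a better partition. The double sums run over all
#' ordered pairs including `i = j`, so self-loops (nonzero diagonal) enter
#' the score literally.
#'
#' The implementation aggregates per community (within-community weight and
#' degree sums) rather than evaluating the O(n^2) double sum directly; the
#' two are algebraically identical.
#'
#' @param A Symmetric numeric matrix, or a precomputed [sign_split()].
#' @param labels Integer community labels of length `n`.
#' @return The scalar modularity `Q`.
#' @examples
#' # two disjoint unit triangles, split into the two triangles: Q = 1/2
#' tri <- matrix(1, 3, 3) - diag(3)
#' A <- rbind(cbind(tri, matrix(0, 3, 3)), cbind(matrix(0, 3, 3), tri))
#' weighted_modularity(A, rep(1:2, each = 3))
#' @export
weighted_modularity <- function(A, labels) {
  sp <- if (inherits(A, "sign_split")) A else sign_split(A)
  if (sp$m_plus + sp$m_minus <= 0)
    stop("modularity is undefined for an all-zero network", call. = FALSE)
  labels <- as.integer(labels)
  Qp <- half_modularity(sp$A_plus, sp$d_plus, sp$m_plus, labels)
  Qm <- half_modularity(sp$A_minus, sp$d_minus, sp$m_minus, labels)
  (2 * sp$m_plus * Qp - 2 * sp$m_minus * Qm) /
    (2 * sp$m_plus + 2 * sp$m_minus)
}

# Newman-Girvan modularity of one nonnegative part via community
# aggregates: sum_c [ W_c / 2m - (D_c / 2m)^2 ], W_c including i = j.
half_modularity <- function(Apart, d, m, labels) {
  if (m <= 0) return(0)
  ks <- sort(unique(labels))
  q <- 0
  for (k in ks) {
    idx <- labels == k
    W <- sum(Apart[idx, idx])
    D <- sum(d[idx])
    q <- q + W / (2 * m) - (D / (2 * m))^2
  }
  q
}

#' Weighted-modularity curve over candidate community counts
#'
#' For each `k = 1..K0`, clusters the network into `k` communities (with
#' [ndfa()] by default) and records the generalized weighted modularity of
#' the resulting partition. The estimated number of communities `K_hat` is
#' the smallest `k` attaining the maximum of the curve. With
#' `early_stop = TRUE` the scan stops at the first `k` whose modularity
#' does not exceed `Q(k)` of its predecessor ("increase k until the
#' modularity does not increase"); the default is the full scan, which is
#' the formal argmax definition.
#'
#' The full eigendecomposition of `A` is computed once and reused for
#' every `k`.
#'
#' @param A Symmetric numeric matrix, not all zero.
#' @param K0 Largest candidate number of communities.
#' @param restarts,seed,ordering Passed to [ndfa()]; repetition `k` of the
#'   scan uses seed `seed + k` so the per-`k` clusterings are independent
#'   streams.
#' @param clusterer Function `(A, k, restarts, seed, ...)` returning
#'   integer labels; defaults to [ndfa()].
#' @param early_stop Stop scanning once the curve stops increasing.
#' @return A list of class `"modularity_curve"`: `k` (candidates scanned),
#'   `Q` (modularity values), `K_hat`, `K0`, `labels` (list of partitions
#'   per scanned `k`).
#' @examples
#' spec <- dcdfm_spec(30, 3, rep(1:3, 10), rep(1, 30),
#'                    diag(3) * 0.8 + 0.2, "poisson")
#' curve <- modularity_curve(build_omega(spec), K0 = 6, seed = 1)
#' curve$K_hat
#' @export
modularity_curve <- function(A, K0, restarts = 10, seed = NULL,
                             ordering = c("magnitude", "algebraic"),
                             clusterer = NULL, early_stop = FALSE) {
  ordering <- match.arg(ordering)
  n <- nrow(A)
  if (K0 < 1 || K0 > n)
    stop("`K0` must satisfy 1 <= K0 <= n = ", n, call. = FALSE)
  sp <- sign_split(A)
  if (sp$m_plus + sp$m_minus <= 0)
    stop("modularity is undefined for an all-zero network", call. = FALSE)

  eig <- if (is.null(clusterer) && K0 > 1) eigen(A, symmetric = TRUE)
  Q <- rep(NA_real_, K0)
  labs <- vector("list", K0)
  scanned <- 0L
  for (k in seq_len(K0)) {
    s <- if (is.null(seed)) NULL else seed + k
    lab <- if (is.null(clusterer))
      ndfa(A, k, restarts = restarts, seed = s, ordering = ordering,
           eig = eig)
    else clusterer(A, k, restarts = restarts, seed = s)
    Q[k] <- weighted_modularity(sp, lab)
    labs[[k]] <- lab
    scanned <- k
    if (early_stop && k > 1 && Q[k] <= Q[k - 1]) break
  }
  ks <- seq_len(scanned)
  Qs <- Q[ks]
  structure(list(k = ks, Q = Qs, K_hat = ks[which.max(Qs)], K0 = K0,
                 labels = labs[ks]),
            class = "modularity_curve")
}

#' @export
print.modularity_curve <- function(x, ...) {
  cat(sprintf("Weighted-modularity curve over k = 1..%d (K0 = %d)\n",
              max(x$k), x$K0))
  cat(sprintf("  K_hat = %d with Q = %.4f\n", x$K_hat, x$Q[x$K_hat]))
  invisible(x)
}

#' Export a modularity curve as a two-column TSV file
#'
#' @param curve A `"modularity_curve"` or fitted `"ndfawm"` object.
#' @param path Output path; columns `k` and `Q`.
#' @return `path`, invisibly.
#' @export
write_modularity_curve <- function(curve, path) {
  utils::write.table(data.frame(k = curve$k, Q = curve$Q), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
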