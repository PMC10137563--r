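#' Specify a degree-corrected distribution-free model (DCDFM)
#'
#' Bundles the parameters of the DCDFM generative model for undirected
#' weighted networks: `n` nodes split into `K` communities by the label
#' vector `labels`, per-node positive heterogeneity `theta`, and a `K x K`
#' symmetric connectivity matrix `P`. Edge weights are drawn from the
#' distribution `family` with expectation `Omega = Theta Z P Z' Theta`,
#' where `Z` is the binary membership matrix and `Theta = diag(theta)`.
#'
#' `P` may contain negative entries only for families whose support allows
#' negative weights (`normal`, `laplace`, `signed`). Its maximum absolute
#' entry is conventionally 1, so that overall scale is carried by `theta`;
#' a deviation triggers a warning unless `strict = TRUE`, in which case it
#' is an error (the simulator's built-in settings use strict specs).
#'
#' @param n Number of nodes (positive integer).
#' @param K True number of communities (positive integer, `K <= n`).
#' @param labels Length-`n` integer vector with entries in `1..K`; every
#'   community must be non-empty.
#' @param theta Length-`n` vector of positive node heterogeneity values.
#' @param P `K x K` symmetric numeric matrix with entries in `[-1, 1]` and
#'   full rank `K`. A scalar is accepted when `K = 1`.
#' @param family Edge-weight distribution: one of `"bernoulli"`,
#'   `"binomial"`, `"poisson"`, `"geometric"`, `"exponential"`, `"normal"`,
#'   `"laplace"`, `"uniform"`, `"signed"`.
#' @param m Number of trials (binomial family only).
#' @param sigma2 Variance (normal and laplace families only).
#' @param strict Logical; promote the `max|P| = 1` convention from a
#'   warning to an error.
#'
#' @return An object of class `"dcdfm_spec"`: a list with components `n`,
#'   `K`, `labels`, `theta`, `P`, `family`, `m`, `sigma2`.
#' @seealso [validate_dcdfm()], [build_omega()], [sample_adjacency()],
#'   [simulate.dcdfm_spec()]
#' @examples
#' spec <- dcdfm_spec(n = 12, K = 2, labels = rep(1:2, each = 6),
#'                    theta = rep(0.8, 12),
#'                    P = matrix(c(1, 0.2, 0.2, 1), 2), family = "bernoulli")
#' Omega <- build_omega(spec)
#' range(Omega)
#' @export
dcdfm_spec <- function(n, K, labels, theta, P, family = c(
                         "bernoulli", "binomial", "poisson", "geometric",
                         "exponential", "normal", "laplace", "uniform",
                         "signed"),
                       m = NULL, sigma2 = NULL, strict = FALSE) {
  family <- match.arg(family)
  n <- as.integer(n)
  K <- as.integer(K)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("`n` must be a positive integer", call. = FALSE)
  if (length(K) != 1L || is.na(K) || K < 1L || K > n)
    stop("`K` must be a positive integer with K <= n", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != n)
    stop("`labels` must have length n = ", n, call. = FALSE)
  theta <- as.numeric(theta)
  if (length(theta) == 1L) theta <- rep(theta, n)
  if (length(theta) != n)
    stop("`theta` must have length n = ", n, call. = FALSE)
  if (is.null(dim(P))) P <- matrix(as.numeric(P), nrow = sqrt(length(P)))
  storage.mode(P) <- "double"

  spec <- structure(
    list(n = n, K = K, labels = labels, theta = theta, P = P,
         family = family, m = if (!is.null(m)) as.integer(m) else NULL,
         sigma2 = if (!is.null(sigma2)) as.numeric(sigma2) else NULL),
    class = "dcdfm_spec")
  validate_dcdfm(spec, strict = strict, stop_on_error = TRUE)
  spec
}

#' Validate a DCDFM specification
#'
#' Checks structural invariants (label range, non-empty communities,
#' positive `theta`, symmetric full-rank `P` with entries in `[-1, 1]`) and
#' the family-specific constraints on the expectation matrix `Omega`:
#'
#' * `bernoulli`: `P >= 0` and all `Omega` in `[0, 1]` (edge probabilities);
#' * `binomial`: `P >= 0` and all `Omega / m` in `[0, 1]`;
#' * `poisson`: all `Omega >= 0`;
#' * `geometric`: `P > 0` and all `Omega >= 1` (success probability
#'   `1/Omega` must lie in `(0, 1]`);
#' * `exponential`: `P > 0` (rates `1/Omega` must be positive);
#' * `normal`, `laplace`: no sign constraint, `sigma2 > 0` required;
#' * `uniform`: `P >= 0`;
#' * `signed`: all `|Omega| <= 1` (edge-sign probabilities `(1 ± Omega)/2`).
#'
#' The convention `max|P| = 1` (scale carried by `theta`) is reported as a
#' warning-level finding unless `strict = TRUE`.
#'
#' @param spec A `"dcdfm_spec"` object (or an unclassed list with the same
#'   fields).
#' @param strict Logical; treat the `max|P| = 1` convention as an error.
#' @param stop_on_error Logical; if `TRUE`, stop with the first error
#'   message instead of returning a report.
#' @return Invisibly, a list with `ok` (logical), `errors` and `warnings`
#'   (character vectors of findings).
#' @examples
#' spec <- dcdfm_spec(4, 2, c(1, 1, 2, 2), rep(0.5, 4),
#'                    matrix(c(1, 0.3, 0.3, 1), 2), "poisson")
#' validate_dcdfm(spec)$ok
#' @export
validate_dcdfm <- function(spec, strict = FALSE, stop_on_error = FALSE) {
  errs <- character()
  warns <- character()
  n <- spec$n; K <- spec$K; P <- spec$P

  if (any(is.na(spec$labels)) || any(spec$labels < 1L) ||
      any(spec$labels > K))
    errs <- c(errs, sprintf("labels must lie in {1..%d}", K))
  else if (length(unique(spec$labels)) < K)
    errs <- c(errs, "every community 1..K must be non-empty")
  if (any(!is.finite(spec$theta)) || any(spec$theta <= 0))
    errs <- c(errs, "all theta values must be positive and finite")
  if (!is.matrix(P) || nrow(P) != K || ncol(P) != K)
    errs <- c(errs, sprintf("P must be a %d x %d matrix", K, K))
  else {
    if (!isSymmetric(unname(P), tol = 1e-12))
      errs <- c(errs, "P must be symmetric")
    if (any(abs(P) > 1 + 1e-12))
      errs <- c(errs, "entries of P must lie in [-1, 1]")
    sv <- svd(P, nu = 0, nv = 0)$d
    if (sv[K] <= 1e-10 * sv[1])
      errs <- c(errs, sprintf("P must have full rank %d", K))
    if (abs(max(abs(P)) - 1) > 1e-12) {
      msg <- sprintf("max|P| is %.6g, not 1; overall scale is conventionally carried by theta",
                     max(abs(P)))
      if (strict) errs <- c(errs, msg) else warns <- c(warns, msg)
    }
  }

  if (length(errs) == 0L) {
    omega <- build_omega(spec, check = FALSE)
    fam <- spec$family
    omin <- min(omega); omax <- max(omega)
    bad <- function(test, fmt, ...) if (test) errs <<- c(errs, sprintf(fmt, ...))
    switch(fam,
      bernoulli = {
        bad(any(P < 0), "bernoulli family requires P >= 0")
        bad(omin < 0 || omax > 1,
            "bernoulli family requires Omega in [0,1]; range is [%.4g, %.4g]",
            omin, omax)
      },
      binomial = {
        bad(is.null(spec$m) || spec$m < 1L,
            "binomial family requires a positive trial count m")
        bad(any(P < 0), "binomial family requires P >= 0")
        if (!is.null(spec$m) && spec$m >= 1L)
          bad(omin < 0 || omax > spec$m,
              "binomial family requires Omega/m in [0,1]; Omega range is [%.4g, %.4g], m = %d",
              omin, omax, spec$m)
      },
      poisson = bad(omin < 0, "poisson family requires Omega >= 0; min is %.4g", omin),
      geometric = {
        bad(any(P <= 0), "geometric family requires P > 0")
        bad(omin < 1,
            "geometric family requires Omega >= 1 (success prob 1/Omega in (0,1]); min is %.4g",
            omin)
      },
      exponential = bad(any(P <= 0), "exponential family requires P > 0"),
      normal = bad(is.null(spec$sigma2) || spec$sigma2 <= 0,
                   "normal family requires a positive variance sigma2"),
      laplace = bad(is.null(spec$sigma2) || spec$sigma2 <= 0,
                    "laplace family requires a positive variance sigma2"),
      uniform = bad(any(P < 0), "uniform family requires P >= 0"),
      signed = bad(max(abs(omega)) > 1 + 1e-12,
                   "signed family requires |Omega| <= 1; max |Omega| is %.4g",
                   max(abs(omega)))
    )
  }

  if (stop_on_error && length(errs))
    stop("invalid DCDFM specification:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  for (w in warns) warning(w, call. = FALSE)
  invisible(list(ok = length(errs) == 0L, errors = errs, warnings = warns))
}

#' Community membership matrix from a label vector
#'
#' @param labels Length-`n` vector with entries in `1..K`.
#' @param K Number of communities.
#' @return An `n x K` binary matrix `Z` with `Z[i, k] = 1` iff
#'   `labels[i] == k`; each row sums to one and column `k` sums to the size
#'   of community `k`.
#' @examples
#' build_membership(c(1, 1, 2), 2)
#' @export
build_membership <- function(labels, K) {
  labels <- as.integer(labels)
  K <- as.integer(K)
  if (any(is.na(labels)) || any(labels < 1L) || any(labels > K))
    stop("labels must lie in {1..", K, "}", call. = FALSE)
  Z <- matrix(0, length(labels), K)
  Z[cbind(seq_along(labels), labels)] <- 1
  Z
}

#' Expected adjacency matrix of a DCDFM specification
#'
#' Computes `Omega = Theta Z P Z' Theta`, i.e.
#' `Omega[i, j] = theta[i] * theta[j] * P[labels[i], labels[j]]`. `Omega`
#' is symmetric with rank at most `K`.
#'
#' @param spec A `"dcdfm_spec"` object.
#' @param check Validate the spec first (default `TRUE`).
#' @return The `n x n` numeric matrix `Omega`.
#' @export
build_omega <- function(spec, check = TRUE) {
  if (check) validate_dcdfm(spec, stop_on_error = TRUE)
  block <- spec$P[spec$labels, spec$labels, drop = FALSE]
  spec$theta * block * rep(spec$theta, each = spec$n)
}

#' @export
print.dcdfm_spec <- function(x, ...) {
  cat("DCDFM specification\n")
  cat(sprintf("  n = %d nodes, K = %d communities (sizes: %s)\n",
              x$n, x$K, paste(tabulate(x$labels, x$K), collapse = ", ")))
  cat(sprintf("  family = %s%s%s\n", x$family,
              if (!is.null(x$m)) sprintf(", m = %d", x$m) else "",
              if (!is.null(x$sigma2)) sprintf(", sigma2 = %g", x$sigma2) else ""))
  cat(sprintf("  theta in [%.4g, %.4g]; max|P| = %.4g\n",
              min(x$theta), max(x$theta), max(abs(x$P))))
  invisible(x)
}

#' Write a DCDFM specification to a flat YAML config file
#'
#' Serializes all model parameters (`P` in row-major order) so that
#' [read_dcdfm_spec()] reconstructs an identical spec.
#'
#' @param spec A `"dcdfm_spec"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dcdfm_spec <- function(spec, path) {
  cfg <- list(n = spec$n, K = spec$K, labels = spec$labels,
              theta = spec$theta,
              P = as.vector(t(spec$P)), family = spec$family)
  if (!is.null(spec$m)) cfg$m <- spec$m
  if (!is.null(spec$sigma2)) cfg$sigma2 <- spec$sigma2
  yaml::write_yaml(cfg, path, precision = 17L)
  invisible(path)
}

#' Read a DCDFM specification from a flat YAML config file
#'
#' @param path File written by [write_dcdfm_spec()] (keys: `n`, `K`,
#'   `labels`, `theta`, `P` as a row-major list, `family`, optionally `m`
#'   and `sigma2`).
#' @return A `"dcdfm_spec"` object.
#' @export
read_dcdfm_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  dcdfm_spec(n = cfg$n, K = cfg$K, labels = cfg$labels, theta = cfg$theta,
             P = matrix(cfg$P, nrow = cfg$K, byrow = TRUE),
             family = cfg$family, m = cfg$m, sigma2 = cfg$sigma2)
}
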