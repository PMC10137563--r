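#' Draw node heterogeneity values from the sparsity parameter rho
#'
#' Two conventions for the heterogeneity vector `theta` are used by the
#' built-in simulation settings: `theta[i] = U_i * rho` with
#' `U_i ~ Uniform(0, 1)` i.i.d. (`"uniform_scaled"`, the default used for
#' most distribution families), and the homogeneous `theta[i] = rho`
#' (`"constant"`, used for the geometric and signed-network settings, where
#' the model reduces to its distribution-free sub-model).
#'
#' @param n Number of nodes.
#' @param rho Positive sparsity scale.
#' @param mode `"uniform_scaled"` or `"constant"`.
#' @param seed Optional integer seed; when supplied, the draw is
#'   reproducible and the caller's RNG state is left untouched.
#' @return Length-`n` numeric vector of positive values.
#' @examples
#' theta_from_rho(5, 0.5, "constant")
#' @export
theta_from_rho <- function(n, rho, mode = c("uniform_scaled", "constant"),
                           seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0)
    stop("`rho` must be a positive number", call. = FALSE)
  if (mode == "constant") return(rep(rho, n))
  with_seed(seed, stats::runif(n) * rho)
}

# Evaluate `expr` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Laplace deviates with mean mu and variance sigma2, by inverse CDF.
rlaplace_ms <- function(n, mu, sigma2) {
  b <- sqrt(sigma2 / 2)
  u <- stats::runif(n) - 0.5
  mu - b * sign(u) * log1p(-2 * abs(u))
}

#' Sample a weighted adjacency matrix from a DCDFM specification
#'
#' For each unordered pair `i < j`, one edge weight is drawn from the
#' spec's distribution family with expectation `Omega[i, j]` (the uniform
#' family is the one exception: it draws `Uniform(0, Omega[i, j])`, whose
#' mean is `Omega[i, j] / 2` — see the package vignette) and mirrored to
#' `(j, i)`, so the result is exactly symmetric. Family laws:
#'
#' * `bernoulli`: `Bernoulli(Omega_ij)`;
#' * `binomial`: `Binomial(m, Omega_ij / m)`;
#' * `poisson`: `Poisson(Omega_ij)`;
#' * `geometric`: support `{1, 2, ...}` with success probability
#'   `1 / Omega_ij`;
#' * `exponential`: rate `1 / Omega_ij` (mean `Omega_ij`);
#' * `normal`: `Normal(Omega_ij, sigma2)`;
#' * `laplace`: Laplace with mean `Omega_ij` and variance `sigma2`;
#' * `uniform`: `Uniform(0, Omega_ij)`;
#' * `signed`: `+1` with probability `(1 + Omega_ij) / 2`, else `-1`.
#'
#' Diagonal entries are 0 by default (no self-loops); with
#' `sample_diag = TRUE` they are drawn from the same law with expectation
#' `Omega[i, i]`.
#'
#' @param spec A `"dcdfm_spec"` object.
#' @param seed Optional integer seed; identical `(spec, seed)` pairs yield
#'   bit-identical matrices.
#' @param sample_diag Draw the diagonal from the model law instead of
#'   fixing it to 0.
#' @param check Validate the spec first (default `TRUE`).
#' @return An `n x n` symmetric numeric matrix with attributes `"family"`
#'   and (if given) `"seed"`.
#' @examples
#' spec <- dcdfm_spec(10, 2, rep(1:2, 5), rep(0.9, 10),
#'                    matrix(c(1, -0.4, -0.4, 1), 2), "signed")
#' A <- sample_adjacency(spec, seed = 1)
#' all(A %in% c(-1, 0, 1))
#' @export
sample_adjacency <- function(spec, seed = NULL, sample_diag = FALSE,
                             check = TRUE) {
  if (check) validate_dcdfm(spec, stop_on_error = TRUE)
  omega <- build_omega(spec, check = FALSE)
  n <- spec$n
  up <- upper.tri(omega, diag = sample_diag)
  mu <- omega[up]
  draws <- with_seed(seed, draw_family(spec$family, mu, spec))
  if (any(!is.finite(draws)))
    stop("sampler produced non-finite edge weights", call. = FALSE)
  A <- matrix(0, n, n)
  A[up] <- draws
  if (sample_diag) {
    d <- diag(A)
    diag(A) <- 0
    A <- A + t(A)
    diag(A) <- d
  } else {
    A <- A + t(A)
  }
  attr(A, "family") <- spec$family
  if (!is.null(seed)) attr(A, "seed") <- seed
  A
}

draw_family <- function(family, mu, spec) {
  npair <- length(mu)
  switch(family,
    bernoulli = stats::rbinom(npair, 1L, mu),
    binomial = stats::rbinom(npair, spec$m, mu / spec$m),
    poisson = stats::rpois(npair, mu),
    geometric = stats::rgeom(npair, 1 / mu) + 1,
    exponential = stats::rexp(npair, rate = 1 / mu),
    normal = stats::rnorm(npair, mean = mu, sd = sqrt(spec$sigma2)),
    laplace = rlaplace_ms(npair, mu, spec$sigma2),
    uniform = stats::runif(npair, 0, mu),
    signed = 2L * stats::rbinom(npair, 1L, (1 + mu) / 2) - 1L,
    stop("unknown family: ", family, call. = FALSE)
  )
}

#' Simulate adjacency matrices from a DCDFM specification
#'
#' S3 [stats::simulate()] method: draws `nsim` independent adjacency
#' matrices via [sample_adjacency()], seeding replicate `r` with
#' `seed + r - 1` when `seed` is given.
#'
#' @param object A `"dcdfm_spec"` object.
#' @param nsim Number of networks to draw.
#' @param seed Optional integer base seed.
#' @param ... Passed to [sample_adjacency()] (e.g. `sample_diag`).
#' @return A list of `nsim` symmetric adjacency matrices.
#' @export
simulate.dcdfm_spec <- function(object, nsim = 1, seed = NULL, ...) {
  validate_dcdfm(object, stop_on_error = TRUE)
  lapply(seq_len(nsim), function(r) {
    s <- if (is.null(seed)) NULL else seed + r - 1L
    sample_adjacency(object, seed = s, check = FALSE, ...)
  })
}
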