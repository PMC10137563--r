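# Built-in simulation-study settings: nine distribution families, each
# with four sub-settings varying (a) the sparsity scale rho, (b) the true
# community count K, (c) rho with a single community, and (d) the
# off-diagonal connectivity beta. Conventions shared by all settings:
# n = 50 * K nodes (100 * K for signed networks), node labels assigned to
# the K communities with equal probability, heterogeneous theta_i =
# U_i * sqrt(rho) with U_i ~ Uniform(0,1) (homogeneous theta_i =
# sqrt(rho) for the geometric and signed families, where the expectation
# matrix is then exactly rho * Z P Z'), and the candidate cap K0 = 20.
# The sqrt keeps the expectation matrix linear in rho, which is what
# makes each family's stated rho range coincide with its validity range
# (e.g. Bernoulli needs rho <= 1, binomial rho <= m, geometric
# rho * min(P) >= 1, signed rho <= 1).

# connectivity matrices used across settings
P_3x3 <- matrix(c(1, 0.2, 0.3,
                  0.2, 0.8, 0.2,
                  0.3, 0.2, 0.9), 3, 3, byrow = TRUE)
P_3x3_mixed <- matrix(c(1, -0.2, -0.3,
                        -0.2, 0.8, 0.2,
                        -0.3, 0.2, 0.9), 3, 3, byrow = TRUE)
P_offdiag <- function(K, off = 0.2) {
  P <- matrix(off, K, K)
  diag(P) <- 1
  P
}
P_beta <- function(beta) matrix(c(1, beta, beta, 1), 2, 2)

setting_table <- function() {
  beta8 <- seq(0.1, 0.8, by = 0.1)
  beta15 <- seq(-0.5, 0.9, by = 0.1)
  def <- function(id, family, grid_param, grid, K = NA, rho = NA,
                  P_kind, m = NULL, sigma2 = NULL,
                  theta_mode = "uniform_scaled", n_factor = 50L) {
    list(id = id, family = family, grid_param = grid_param, grid = grid,
         K = K, rho = rho, P_kind = P_kind, m = m, sigma2 = sigma2,
         theta_mode = theta_mode, n_factor = n_factor)
  }
  list(
    `1a` = def("1a", "bernoulli", "rho", seq(0.2, 1, 0.1), K = 3, P_kind = "P3"),
    `1b` = def("1b", "bernoulli", "K", 2:6, rho = 0.9, P_kind = "offdiag"),
    `1c` = def("1c", "bernoulli", "rho", seq(0.1, 1, 0.1), K = 1, P_kind = "one"),
    `1d` = def("1d", "bernoulli", "beta", beta8, K = 2, rho = 1, P_kind = "beta"),
    `2a` = def("2a", "binomial", "rho", seq(0.5, 5, 0.5), K = 3, P_kind = "P3", m = 5L),
    `2b` = def("2b", "binomial", "K", 2:6, rho = 2, P_kind = "offdiag", m = 5L),
    `2c` = def("2c", "binomial", "rho", seq(0.5, 5, 0.5), K = 1, P_kind = "one", m = 5L),
    `2d` = def("2d", "binomial", "beta", beta8, K = 2, rho = 1, P_kind = "beta", m = 5L),
    `3a` = def("3a", "poisson", "rho", seq(0.5, 5, 0.5), K = 3, P_kind = "P3"),
    `3b` = def("3b", "poisson", "K", 2:6, rho = 2, P_kind = "offdiag"),
    `3c` = def("3c", "poisson", "rho", seq(0.5, 5, 0.5), K = 1, P_kind = "one"),
    `3d` = def("3d", "poisson", "beta", beta8, K = 2, rho = 2, P_kind = "beta"),
    `4a` = def("4a", "geometric", "rho", 5:15, K = 3, P_kind = "P3",
               theta_mode = "constant"),
    `4b` = def("4b", "geometric", "K", 2:6, rho = 10, P_kind = "offdiag",
               theta_mode = "constant"),
    `4c` = def("4c", "geometric", "rho", seq(2, 20, 2), K = 1, P_kind = "one",
               theta_mode = "constant"),
    `4d` = def("4d", "geometric", "beta", beta8, K = 2, rho = 10, P_kind = "beta",
               theta_mode = "constant"),
    `5a` = def("5a", "exponential", "rho", 1:10, K = 3, P_kind = "P3"),
    `5b` = def("5b", "exponential", "K", 2:6, rho = 5, P_kind = "offdiag"),
    `5c` = def("5c", "exponential", "rho", 1:10, K = 1, P_kind = "one"),
    `5d` = def("5d", "exponential", "beta", beta8, K = 2, rho = 5, P_kind = "beta"),
    `6a` = def("6a", "normal", "rho", 1:10, K = 3, P_kind = "P3mixed", sigma2 = 1),
    `6b` = def("6b", "normal", "K", 2:6, rho = 3, P_kind = "offdiag", sigma2 = 1),
    `6c` = def("6c", "normal", "rho", seq(0.5, 10, 0.5), K = 1, P_kind = "one",
               sigma2 = 1),
    `6d` = def("6d", "normal", "beta", beta15, K = 2, rho = 2, P_kind = "beta",
               sigma2 = 1),
    `7a` = def("7a", "laplace", "rho", 1:10, K = 3, P_kind = "P3mixed", sigma2 = 1),
    `7b` = def("7b", "laplace", "K", 2:6, rho = 3, P_kind = "offdiag", sigma2 = 1),
    `7c` = def("7c", "laplace", "rho", seq(0.5, 10, 0.5), K = 1, P_kind = "one",
               sigma2 = 1),
    `7d` = def("7d", "laplace", "beta", beta15, K = 2, rho = 2, P_kind = "beta",
               sigma2 = 1),
    `8a` = def("8a", "uniform", "rho", seq(2, 20, 2), K = 3, P_kind = "P3"),
    `8b` = def("8b", "uniform", "K", 2:6, rho = 0.3, P_kind = "offdiag"),
    `8c` = def("8c", "uniform", "rho", seq(2, 20, 2), K = 1, P_kind = "one"),
    `8d` = def("8d", "uniform", "beta", beta8, K = 2, rho = 1, P_kind = "beta"),
    `9a` = def("9a", "signed", "rho", seq(0.1, 1, 0.1), K = 3, P_kind = "P3mixed",
               theta_mode = "constant", n_factor = 100L),
    `9b` = def("9b", "signed", "K", 2:6, rho = 0.5, P_kind = "offdiag",
               theta_mode = "constant", n_factor = 100L),
    `9c` = def("9c", "signed", "rho", seq(0.1, 1, 0.1), K = 1, P_kind = "one",
               theta_mode = "constant", n_factor = 100L),
    `9d` = def("9d", "signed", "beta", beta15, K = 2, rho = 0.5, P_kind = "beta",
               theta_mode = "constant", n_factor = 100L)
  )
}

#' List the identifiers of the built-in simulation settings
#'
#' @return Character vector `"1a"`, `"1b"`, ..., `"9d"`.
#' @export
experiment_ids <- function() names(setting_table())

#' Retrieve a built-in simulation-study setting
#'
#' Returns the exact parameterization of one of the 36 built-in
#' simulation settings. Settings are grouped by distribution family
#' (1 Bernoulli, 2 binomial, 3 Poisson, 4 geometric, 5 exponential,
#' 6 normal, 7 Laplace, 8 uniform, 9 signed) and sub-setting: (a) a grid
#' over the sparsity scale `rho` with `K = 3`, (b) a grid over the true
#' community count `K`, (c) a `rho` grid with a single community
#' (`K = 1`), and (d) a grid over the off-diagonal connectivity `beta`
#' with `K = 2`.
#'
#' @param id Setting identifier, e.g. `"1a"` or `"9d"`; see
#'   [experiment_ids()].
#' @return An object of class `"experiment_setting"`: a list with `id`,
#'   `family`, `grid_param` (`"rho"`, `"K"` or `"beta"`), `grid` (its
#'   values), fixed parameters (`K`, `rho`, `m`, `sigma2`), `theta_mode`
#'   and `n_factor` (nodes per community).
#' @examples
#' builtin_setting("4b")
#' @export
builtin_setting <- function(id) {
  tab <- setting_table()
  if (!id %in% names(tab))
    stop("unknown setting id '", id, "'; see experiment_ids()",
         call. = FALSE)
  structure(tab[[id]], class = "experiment_setting")
}

#' @export
print.experiment_setting <- function(x, ...) {
  cat(sprintf("Simulation setting %s: %s family\n", x$id, x$family))
  cat(sprintf("  grid over %s: %s\n", x$grid_param,
              paste(format(x$grid), collapse = ", ")))
  fixed <- c(if (!is.na(x$K)) sprintf("K = %d", x$K),
             if (!is.na(x$rho)) sprintf("rho = %g", x$rho),
             if (!is.null(x$m)) sprintf("m = %d", x$m),
             if (!is.null(x$sigma2)) sprintf("sigma2 = %g", x$sigma2),
             sprintf("n = %d * K", x$n_factor),
             sprintf("theta: %s", x$theta_mode))
  cat("  fixed:", paste(fixed, collapse = "; "), "\n")
  invisible(x)
}

# Materialize a DCDFM spec at one grid value; labels and theta are drawn
# from the current RNG stream.
setting_spec <- function(setting, gval) {
  K <- if (setting$grid_param == "K") as.integer(gval) else as.integer(setting$K)
  rho <- if (setting$grid_param == "rho") gval else setting$rho
  beta <- if (setting$grid_param == "beta") gval else NA
  P <- switch(setting$P_kind,
    P3 = P_3x3,
    P3mixed = P_3x3_mixed,
    offdiag = P_offdiag(K),
    beta = P_beta(beta),
    one = matrix(1, 1, 1))
  n <- setting$n_factor * K
  repeat {
    labels <- sample.int(K, n, replace = TRUE)
    if (length(unique(labels)) == K) break
  }
  theta <- theta_from_rho(n, sqrt(rho), setting$theta_mode)
  dcdfm_spec(n = n, K = K, labels = labels, theta = theta, P = P,
             family = setting$family, m = setting$m,
             sigma2 = setting$sigma2, strict = TRUE)
}

#' Run a simulation study and compute the accuracy rate
#'
#' For every grid point of a setting and every repetition, draws a fresh
#' DCDFM network (new labels and `theta` each repetition), runs the nDFAwm
#' estimator with candidate cap `K0`, and records the estimated community
#' count. The accuracy rate at a grid point is the fraction of repetitions
#' whose estimate equals the true `K`. Repetition `r` at grid point `g`
#' uses seed `seed_base + 10000 * g + r`, so grid points are independent
#' reproducible streams.
#'
#' @param setting An `"experiment_setting"` (see [builtin_setting()]) or
#'   a setting id string.
#' @param reps Repetitions per grid point (default 20).
#' @param seed_base Integer base seed.
#' @param K0 Candidate cap for the estimator (default 20).
#' @param restarts k-means restarts per candidate.
#' @return An object of class `"experiment_result"`: a list with `id`,
#'   `grid_param`, `accuracy` (a `data.frame` with columns `experiment`,
#'   `grid_param`, `grid_value`, `reps`, `accuracy`), `K_hat` (list of
#'   per-repetition estimates per grid point), `K_true` (per grid point),
#'   `reps`, `seed_base`.
#' @examples
#' \donttest{
#' res <- run_experiment("1b", reps = 3, seed_base = 1)
#' res$accuracy
#' }
#' @export
run_experiment <- function(setting, reps = 20, seed_base = 1L, K0 = 20L,
                           restarts = 10L) {
  if (is.character(setting)) setting <- builtin_setting(setting)
  if (reps < 1) stop("`reps` must be at least 1", call. = FALSE)
  G <- length(setting$grid)
  K_hat <- vector("list", G)
  K_true <- integer(G)
  for (g in seq_len(G)) {
    gval <- setting$grid[g]
    est <- integer(reps)
    for (r in seq_len(reps)) {
      seed <- as.integer(seed_base + 10000L * g + r)
      est[r] <- with_seed(seed, {
        spec <- setting_spec(setting, gval)
        A <- sample_adjacency(spec, check = FALSE)
        modularity_curve(A, K0 = min(K0, spec$n), restarts = restarts,
                         seed = seed)$K_hat
      })
    }
    K_hat[[g]] <- est
    K_true[g] <- if (setting$grid_param == "K") as.integer(gval)
                 else as.integer(setting$K)
  }
  acc <- vapply(seq_len(G), function(g) mean(K_hat[[g]] == K_true[g]),
                numeric(1))
  accuracy <- data.frame(experiment = setting$id,
                         grid_param = setting$grid_param,
                         grid_value = setting$grid,
                         reps = reps, accuracy = acc)
  structure(list(id = setting$id, grid_param = setting$grid_param,
                 accuracy = accuracy, K_hat = K_hat, K_true = K_true,
                 reps = reps, seed_base = seed_base),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Simulation setting %s: accuracy over %d repetitions\n",
              x$id, x$reps))
  print(x$accuracy, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write experiment accuracies as a tidy TSV table
#'
#' @param result An `"experiment_result"` object.
#' @param path Output path; columns `experiment`, `grid_param`,
#'   `grid_value`, `reps`, `accuracy`. With `long = TRUE`, one row per
#'   repetition (`grid_value`, `rep`, `K_true`, `K_hat`) instead.
#' @param long Write the per-repetition long format.
#' @return `path`, invisibly.
#' @export
write_experiment_result <- function(result, path, long = FALSE) {
  tab <- if (!long) result$accuracy else {
    G <- length(result$K_hat)
    do.call(rbind, lapply(seq_len(G), function(g)
      data.frame(experiment = result$id,
                 grid_param = result$grid_param,
                 grid_value = result$accuracy$grid_value[g],
                 rep = seq_len(result$reps),
                 K_true = result$K_true[g],
                 K_hat = result$K_hat[[g]])))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Plot accuracy against the grid parameter for a simulation study
#'
#' @param x An `"experiment_result"` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.experiment_result <- function(x, ...) {
  args <- list(x = x$accuracy$grid_value, y = x$accuracy$accuracy,
               type = "b", ylim = c(0, 1), xlab = x$grid_param,
               ylab = "accuracy rate", ...)
  if (is.null(args$main))
    args$main <- sprintf("Setting %s (%d reps)", x$id, x$reps)
  do.call(graphics::plot, args)
  invisible(x)
}
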