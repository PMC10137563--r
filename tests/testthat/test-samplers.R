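test_that("theta draws follow the requested convention", {
  expect_equal(theta_from_rho(3, 0.5, "constant"), rep(0.5, 3))
  th <- theta_from_rho(200, 2, "uniform_scaled", seed = 4)
  expect_true(all(th > 0 & th < 2))
  # law of large numbers: mean of Uniform(0, 1) scaled by rho = 1
  th_big <- theta_from_rho(10000, 1, "uniform_scaled", seed = 8)
  expect_lt(abs(mean(th_big) - 0.5), 0.02)
  expect_error(theta_from_rho(5, -1), "positive")
})

test_that("sampled adjacency matrices are symmetric, finite and reproducible", {
  set.seed(31)
  fams <- list(
    bernoulli = planted_spec(12, 2, "bernoulli", rho = 0.9),
    binomial = planted_spec(12, 2, "binomial", rho = 0.9, m = 4L),
    poisson = planted_spec(12, 2, "poisson", rho = 2),
    geometric = dcdfm_spec(12, 2, rep(1:2, 6), rep(3, 12),
                           matrix(c(1, .5, .5, 1), 2), "geometric"),
    exponential = planted_spec(12, 2, "exponential", rho = 2),
    normal = planted_spec(12, 2, "normal", sigma2 = 1),
    laplace = planted_spec(12, 2, "laplace", sigma2 = 1),
    uniform = planted_spec(12, 2, "uniform", rho = 2),
    signed = dcdfm_spec(12, 2, rep(1:2, 6), rep(0.8, 12),
                        matrix(c(1, -.5, -.5, 1), 2), "signed"))
  for (fam in names(fams)) {
    A <- sample_adjacency(fams[[fam]], seed = 101)
    expect_true(isSymmetric(unname(A)), label = paste(fam, "symmetric"))
    expect_true(all(is.finite(A)), label = paste(fam, "finite"))
    expect_equal(diag(A), rep(0, 12))
    A2 <- sample_adjacency(fams[[fam]], seed = 101)
    expect_identical(c(A), c(A2), label = paste(fam, "reproducible"))
    A3 <- sample_adjacency(fams[[fam]], seed = 102)
    expect_false(identical(c(A), c(A3)))
  }
  # support constraints
  G <- sample_adjacency(fams$geometric, seed = 1)
  expect_true(all(G[upper.tri(G)] >= 1))
  S <- sample_adjacency(fams$signed, seed = 1)
  expect_true(all(S[upper.tri(S)] %in% c(-1, 1)))
  B <- sample_adjacency(fams$binomial, seed = 1)
  expect_true(all(B %in% 0:4))
})

test_that("degenerate expectations force deterministic draws", {
  # bernoulli with Omega = 1 everywhere: complete unit graph
  s <- dcdfm_spec(6, 1, rep(1, 6), rep(1, 6), matrix(1), "bernoulli")
  A <- sample_adjacency(s, seed = 7)
  expect_equal(matrix(A, 6, 6), matrix(1, 6, 6) - diag(6))
  # signed with Omega = 1 everywhere: all +1 off-diagonal
  s2 <- dcdfm_spec(6, 1, rep(1, 6), rep(1, 6), matrix(1), "signed")
  A2 <- sample_adjacency(s2, seed = 7)
  expect_equal(matrix(A2, 6, 6), matrix(1, 6, 6) - diag(6))
})

test_that("empirical edge-weight means match the expectation matrix", {
  # moderate Monte-Carlo check per family (the deeper 1e4-draw sweep is
  # in the acceptance suite): mean over draws within 5 SE entrywise
  set.seed(41)
  specs <- list(
    poisson = planted_spec(8, 2, "poisson", rho = 2),
    normal = planted_spec(8, 2, "normal", sigma2 = 1),
    laplace = planted_spec(8, 2, "laplace", sigma2 = 1))
  for (fam in names(specs)) {
    spec <- specs[[fam]]
    Om <- build_omega(spec)
    reps <- 2000
    acc <- matrix(0, spec$n, spec$n)
    for (r in seq_len(reps))
      acc <- acc + sample_adjacency(spec, seed = 5000 + r, check = FALSE)
    up <- upper.tri(Om)
    sds <- switch(fam, poisson = sqrt(Om[up]),
                  normal = sqrt(spec$sigma2 + 0 * Om[up]),
                  laplace = sqrt(spec$sigma2 + 0 * Om[up]))
    err <- abs(acc[up] / reps - Om[up]) / (sds / sqrt(reps))
    expect_lt(max(err), 5, label = paste(fam, "entrywise mean"))
  }
})

test_that("laplace draws have the stated mean and variance", {
  x <- ndfawm:::with_seed(3, ndfawm:::rlaplace_ms(2e5, mu = 1.5, sigma2 = 4))
  expect_lt(abs(mean(x) - 1.5), 0.02)
  expect_lt(abs(var(x) - 4), 0.1)
})

test_that("the diagonal can optionally be sampled from the model law", {
  s <- dcdfm_spec(10, 1, rep(1, 10), rep(2, 10), matrix(1), "poisson")
  A <- sample_adjacency(s, seed = 9, sample_diag = TRUE)
  expect_true(isSymmetric(unname(A)))
  expect_gt(sum(diag(A)), 0)
})

test_that("simulate() returns independent reproducible replicates", {
  s <- planted_spec(10, 2, "poisson", rho = 2)
  sims <- simulate(s, nsim = 3, seed = 50)
  expect_length(sims, 3)
  expect_false(identical(sims[[1]], sims[[2]]))
  sims2 <- simulate(s, nsim = 3, seed = 50)
  expect_identical(sims, sims2)
})
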