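test_that("membership matrix encodes labels one-hot with correct counts", {
  expect_equal(build_membership(c(1, 1, 2), 2),
               rbind(c(1, 0), c(1, 0), c(0, 1)))
  expect_equal(build_membership(1:3, 3), diag(3))

  set.seed(11)
  for (K in c(2, 4)) {
    lab <- sample.int(K, 37, replace = TRUE)
    Z <- build_membership(lab, K)
    expect_equal(rowSums(Z), rep(1, 37))
    expect_equal(colSums(Z),
                 vapply(seq_len(K), function(k) sum(lab == k), numeric(1)))
  }
  expect_error(build_membership(c(1, 3), 2), "labels")
})

test_that("expectation matrix equals Theta Z P Z' Theta and has rank <= K", {
  # unit parameters: all-ones matrix
  s1 <- dcdfm_spec(2, 1, c(1, 1), c(1, 1), matrix(1), "poisson")
  expect_equal(build_omega(s1), matrix(1, 2, 2))

  # two blocks, constant theta: closed form rho^2 * ((1, b), (b, 1))
  rho <- 0.7; b <- 0.4
  s2 <- dcdfm_spec(2, 2, c(1, 2), c(rho, rho), matrix(c(1, b, b, 1), 2),
                   "poisson")
  expect_equal(build_omega(s2), rho^2 * matrix(c(1, b, b, 1), 2))

  # random spec vs the independent triple-product route
  set.seed(21)
  lab <- rep(1:3, 4)
  theta <- runif(12) + 0.2
  P <- matrix(c(1, .2, .3, .2, .8, .2, .3, .2, .9), 3, byrow = TRUE)
  s3 <- dcdfm_spec(12, 3, lab, theta, P, "poisson")
  Om <- build_omega(s3)
  Z <- build_membership(lab, 3)
  expect_equal(Om, diag(theta) %*% Z %*% P %*% t(Z) %*% diag(theta))
  expect_true(isSymmetric(Om))
  sv <- svd(Om)$d
  expect_lt(sv[4], 1e-10 * sv[1])
  expect_gt(sv[3], 1e-10 * sv[1])
})

test_that("constant theta reduces the model to a scaled block matrix", {
  s <- dcdfm_spec(9, 3, rep(1:3, 3), rep(0.5, 9),
                  matrix(c(1, .2, .3, .2, .8, .2, .3, .2, .9), 3,
                         byrow = TRUE), "poisson")
  Z <- build_membership(s$labels, 3)
  expect_equal(build_omega(s), 0.25 * Z %*% s$P %*% t(Z))
})

test_that("family constraints accept and reject per the model rules", {
  P2 <- matrix(c(1, .2, .2, 1), 2)
  # bernoulli: an expectation above 1 is not a probability
  expect_error(
    dcdfm_spec(4, 2, c(1, 1, 2, 2), rep(1.1, 4), P2, "bernoulli"),
    "bernoulli.*\\[0,1\\]")
  # geometric: success probability 1/Omega needs Omega >= 1
  expect_error(
    dcdfm_spec(4, 2, c(1, 1, 2, 2), rep(sqrt(2.5), 4), P2, "geometric"),
    "geometric.*min is 0.5")
  # signed: |Omega| <= 1 accepted at the boundary
  s <- dcdfm_spec(4, 2, c(1, 1, 2, 2), rep(1, 4),
                  matrix(c(1, -.5, -.5, 1), 2), "signed")
  expect_true(validate_dcdfm(s)$ok)
  expect_error(
    dcdfm_spec(4, 2, c(1, 1, 2, 2), rep(1.2, 4),
               matrix(c(1, -.5, -.5, 1), 2), "signed"),
    "signed")
  # sign constraints on P
  expect_error(
    dcdfm_spec(4, 2, c(1, 1, 2, 2), rep(0.5, 4),
               matrix(c(1, -.2, -.2, 1), 2), "uniform"),
    "uniform.*P >= 0")
  expect_error(
    dcdfm_spec(4, 2, c(1, 1, 2, 2), rep(0.5, 4),
               matrix(c(1, 0, 0, 1), 2), "exponential"),
    "exponential.*P > 0")
  # normal family allows negative P but needs a variance
  expect_error(
    dcdfm_spec(4, 2, c(1, 1, 2, 2), rep(0.5, 4),
               matrix(c(1, -.2, -.2, 1), 2), "normal"),
    "sigma2")
  expect_silent(
    dcdfm_spec(4, 2, c(1, 1, 2, 2), rep(0.5, 4),
               matrix(c(1, -.2, -.2, 1), 2), "normal", sigma2 = 2))
})

test_that("structural violations are rejected with reasons", {
  P2 <- matrix(c(1, .2, .2, 1), 2)
  expect_error(dcdfm_spec(4, 2, c(1, 1, 1, 1), rep(.5, 4), P2, "poisson"),
               "non-empty")
  expect_error(dcdfm_spec(4, 2, c(1, 1, 2, 2), c(.5, .5, -1, .5), P2,
                          "poisson"), "theta")
  expect_error(dcdfm_spec(4, 2, c(1, 1, 2, 2), rep(.5, 4),
                          matrix(c(1, .2, .4, 1), 2), "poisson"),
               "symmetric")
  # rank-deficient P
  expect_error(dcdfm_spec(4, 2, c(1, 1, 2, 2), rep(.5, 4),
                          matrix(1, 2, 2), "poisson"), "rank")
  # max|P| != 1 is a warning for user specs, an error under strict
  expect_warning(dcdfm_spec(4, 2, c(1, 1, 2, 2), rep(.5, 4),
                            0.5 * P2, "poisson"), "max\\|P\\|")
  expect_error(dcdfm_spec(4, 2, c(1, 1, 2, 2), rep(.5, 4),
                          0.5 * P2, "poisson", strict = TRUE), "max\\|P\\|")
})

test_that("every built-in simulation setting validates across its grid", {
  set.seed(99)
  for (id in experiment_ids()) {
    st <- builtin_setting(id)
    for (g in st$grid) {
      spec <- ndfawm:::setting_spec(st, g)
      expect_true(validate_dcdfm(spec)$ok,
                  label = sprintf("setting %s at %s = %g valid", id,
                                  st$grid_param, g))
    }
  }
})

test_that("specs round-trip through the flat YAML config format", {
  set.seed(5)
  s <- planted_spec(15, 3, family = "laplace", sigma2 = 2)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_dcdfm_spec(s, path)
  s2 <- read_dcdfm_spec(path)
  expect_equal(s2$labels, s$labels)
  expect_equal(s2$theta, s$theta)
  expect_equal(s2$P, s$P)
  expect_equal(s2$family, s$family)
  expect_equal(s2$sigma2, s$sigma2)
})
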