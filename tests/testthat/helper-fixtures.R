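# Shared fixtures and independent oracles, built in code.

# literal double-sum evaluation of the generalized weighted modularity:
# Q+ and Q- as ordered double sums over all (i, j) including i = j
modularity_oracle <- function(A, labels) {
  Ap <- pmax(A, 0)
  Am <- pmax(-A, 0)
  dp <- rowSums(Ap)
  dm <- rowSums(Am)
  mp <- sum(dp) / 2
  mm <- sum(dm) / 2
  delta <- outer(labels, labels, "==")
  Qp <- if (mp > 0) sum((Ap - outer(dp, dp) / (2 * mp)) * delta) / (2 * mp) else 0
  Qm <- if (mm > 0) sum((Am - outer(dm, dm) / (2 * mm)) * delta) / (2 * mm) else 0
  (2 * mp * Qp - 2 * mm * Qm) / (2 * mp + 2 * mm)
}

# all set partitions of n items into at most `max_blocks` blocks, as
# canonical (restricted-growth) label vectors
all_partitions <- function(n, max_blocks = 3) {
  out <- list()
  grow <- function(lab, used) {
    if (length(lab) == n) {
      out[[length(out) + 1L]] <<- lab
      return(invisible())
    }
    for (k in seq_len(min(used + 1L, max_blocks)))
      grow(c(lab, k), max(used, k))
  }
  grow(integer(0), 0L)
  out
}

# random symmetric matrix with mixed-sign weights and zero diagonal
random_signed_matrix <- function(n) {
  A <- matrix(stats::rnorm(n * n), n, n)
  A[sample(n * n, floor(n * n / 4))] <- 0
  A <- A + t(A)
  diag(A) <- 0
  A
}

# planted two- or three-block DCDFM spec with heterogeneous theta
planted_spec <- function(n, K, family = "poisson", rho = 1,
                         off = 0.2, sigma2 = NULL, m = NULL) {
  P <- matrix(off, K, K)
  diag(P) <- 1
  dcdfm_spec(n, K, rep(seq_len(K), length.out = n),
             theta = stats::runif(n) * 0.9 * rho + 0.1 * rho,
             P = P, family = family, sigma2 = sigma2, m = m)
}

# do two label vectors describe the same partition (up to renaming)?
same_partition <- function(a, b) {
  canon <- function(x) match(x, unique(x))
  identical(canon(as.integer(a)), canon(as.integer(b)))
}
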