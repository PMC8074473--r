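test_that("marginal covariance C_h matches its definition", {
  expect_equal(cov_matrix_C(matrix(1, 1, 1), matrix(0, 1, 1)),
               matrix(1, 1, 1))
  expect_equal(cov_matrix_C(matrix(1, 1, 1), matrix(1, 1, 1)),
               matrix(2, 1, 1))
  expect_equal(cov_matrix_C(matrix(c(1, 2), 1), diag(2)), matrix(6, 1, 1))
  set.seed(4)
  X <- matrix(rnorm(12), 4, 3)
  A <- matrix(rnorm(9), 3)
  C <- cov_matrix_C(X, crossprod(A) + diag(3))
  expect_equal(C, t(C))
  expect_true(all(eigen(C, only.values = TRUE)$values >= 1 - 1e-12))
  expect_error(cov_matrix_C(matrix(1, 1, 2), matrix(1, 1, 1)), "dimension")
})

test_that("Delta^2 agrees with the dense-inverse oracle", {
  # scalar instance: y = 1, X = 1, mu = 0, Sigma = 1 => 1/(1+1) = 0.5
  seg1 <- list(list(y = 1, X = matrix(1, 1, 1)))
  mom1 <- list(list(mu = 0, Sigma = matrix(1, 1, 1)))
  expect_equal(delta_squared(seg1, mom1), 0.5)

  # zero residual when y_h = X_h mu_h
  set.seed(11)
  segs <- random_segments(H = 2L, Th = 5L, k = 2L)
  moms <- random_moments(segs)
  for (h in seq_along(segs)) {
    segs[[h]]$y <- drop(segs[[h]]$X %*% moms[[h]]$mu)
  }
  expect_equal(delta_squared(segs, moms), 0, tolerance = 1e-12)

  # random instances match the explicit T_h x T_h inverse
  for (seed in 1:6) {
    set.seed(seed)
    segs <- random_segments(H = sample(1:3, 1), Th = sample(3:6, 1),
                            k = sample(0:2, 1))
    moms <- random_moments(segs)
    expect_equal(delta_squared(segs, moms),
                 dense_delta_squared(segs, moms), tolerance = 1e-10)
  }

  # invariance under observation reordering within a segment
  set.seed(21)
  segs <- random_segments(H = 1L, Th = 6L, k = 1L)
  moms <- random_moments(segs)
  perm <- sample(6)
  segs_p <- list(list(y = segs[[1]]$y[perm], X = segs[[1]]$X[perm, ]))
  expect_equal(delta_squared(segs, moms), delta_squared(segs_p, moms))
})

test_that("log marginal likelihood matches dense linear algebra", {
  # same formula evaluated with explicit T_h x T_h determinants/inverses
  noise <- noise_hyper(0.005, 0.005)
  for (seed in 1:5) {
    set.seed(100 + seed)
    segs <- random_segments(H = sample(1:3, 1), Th = sample(3:6, 1),
                            k = sample(0:2, 1))
    moms <- random_moments(segs)
    Tn <- sum(vapply(segs, function(s) length(s$y), numeric(1)))
    ld <- sum(vapply(seq_along(segs), function(h) {
      dense_logdet_C(segs[[h]], moms[[h]]$Sigma)
    }, numeric(1)))
    dense <- lgamma(Tn / 2 + 0.005) - lgamma(0.005) -
      (Tn / 2) * log(pi) + 0.005 * log(2 * 0.005) - ld / 2 -
      (Tn / 2 + 0.005) * log(2 * 0.005 + dense_delta_squared(segs, moms))
    expect_equal(log_marginal_likelihood(segs, moms, noise), dense,
                 tolerance = 1e-10)
  }
})

test_that("log marginal likelihood matches brute-force integration", {
  noise <- noise_hyper(2, 2)
  segs <- list(list(y = 0, X = matrix(1, 1, 1)))
  mom <- list(list(mu = 0, Sigma = matrix(1, 1, 1)))
  expect_equal(log_marginal_likelihood(segs, mom, noise),
               quadrature_logml(segs, mom, noise), tolerance = 1e-3)

  segs <- list(list(y = c(0.5, -1, 0.8), X = cbind(1, c(0.2, -0.7, 1.1))))
  mom <- list(list(mu = c(0.1, -0.3), Sigma = diag(c(1.5, 0.7))))
  expect_equal(log_marginal_likelihood(segs, mom, noise),
               quadrature_logml(segs, mom, noise), tolerance = 1e-3)
})

test_that("log marginal likelihood properties hold", {
  noise <- noise_hyper()
  set.seed(33)
  segs <- random_segments(H = 3L, Th = 4L, k = 1L)
  moms <- random_moments(segs)
  # permuting segment order leaves the value unchanged
  perm <- c(3, 1, 2)
  expect_equal(log_marginal_likelihood(segs, moms, noise),
               log_marginal_likelihood(segs[perm], moms[perm], noise))
  # vanishing prior variance pins the weights at their prior means
  tiny <- lapply(moms, function(m) {
    list(mu = m$mu, Sigma = diag(1e-12, length(m$mu)))
  })
  expect_equal(log_marginal_likelihood(segs, tiny, noise),
               pinned_weights_logml(segs, tiny, noise), tolerance = 1e-6)
  expect_error(log_marginal_likelihood(segs, moms, noise_hyper(-1, 1)))
})

test_that("sigma^2 sampler draws from the collapsed conditional", {
  set.seed(5)
  segs <- random_segments(H = 2L, Th = 20L, k = 1L)
  moms <- random_moments(segs)
  noise <- noise_hyper(0.005, 0.005)
  shape <- 0.005 + 40 / 2  # T = 40 observations
  rate <- 0.005 + dense_delta_squared(segs, moms) / 2
  draws <- replicate(1e5, sample_sigma2(segs, moms, noise))
  # empirical mean of sigma^-2 against the gamma mean, 3 SE
  se <- sqrt(shape) / rate / sqrt(1e5)
  expect_lt(abs(mean(1 / draws) - shape / rate), 3 * se)
})

test_that("weight sampler matches the scalar conjugate posterior", {
  seg <- list(y = 1, X = matrix(1, 1, 1))
  mu <- 0
  Sigma <- matrix(1, 1, 1)
  expect_equal(posterior_mean_weights(seg, mu, Sigma), 0.5)
  set.seed(6)
  draws <- replicate(1e5, sample_weights(seg, sigma2 = 1, mu, Sigma))
  expect_lt(abs(mean(draws) - 0.5), 4 * sqrt(0.5 / 1e5))
  expect_lt(abs(var(draws) - 0.5), 4 * sqrt(2 * 0.5^2 / 1e5))
})

test_that("posterior mean interpolates between prior and least squares", {
  set.seed(7)
  seg <- list(y = rnorm(8), X = cbind(1, rnorm(8)))
  mu <- c(2, -1)
  # prior-dominated limit: vanishing prior variance pins the mean at mu
  expect_equal(posterior_mean_weights(seg, mu, diag(1e-12, 2)), mu,
               tolerance = 1e-6)
  # likelihood-dominated limit: diffuse prior recovers least squares
  ls <- drop(solve(crossprod(seg$X), crossprod(seg$X, seg$y)))
  expect_equal(posterior_mean_weights(seg, c(0, 0), diag(1e12, 2)), ls,
               tolerance = 1e-6)
  # zero data with zero prior mean gives the zero vector
  seg0 <- list(y = rep(0, 4), X = cbind(1, rnorm(4)))
  expect_equal(posterior_mean_weights(seg0, c(0, 0), diag(2)), c(0, 0))
})
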