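make_segments <- function(seed = 1, H = 4L, Th = 6L, k = 2L) {
  set.seed(seed)
  random_segments(H = H, Th = Th, k = k)
}

test_that("variant prior moments collapse into each other at the limits", {
  segs <- make_segments(1)
  lu <- 3.2
  lc <- 0.7
  m1 <- prior_moments("M1", coupling_state(lambda_u = lu), segs)
  m2 <- prior_moments("M2", coupling_state(lu, lambda_c = lc), segs)
  # M3 with delta == 0 reproduces M1, with delta == 1 reproduces M2
  m3_0 <- prior_moments("M3", coupling_state(lu, lc, delta = c(0, 0, 0)),
                        segs)
  m3_1 <- prior_moments("M3", coupling_state(lu, lc, delta = c(1, 1, 1)),
                        segs)
  expect_equal(m3_0$moments, m1$moments)
  expect_equal(m3_1$moments, m2$moments)
  # M4 with all lambda_h = lambda_c reproduces M2
  m4 <- prior_moments("M4", coupling_state(lu, lambda_h = rep(lc, 3)), segs)
  expect_equal(m4$moments, m2$moments)

  # uncoupled moments: zero mean, lambda_u I, for every segment
  expect_true(all(vapply(m1$moments, function(m) {
    all(m$mu == 0) && all(m$Sigma == diag(lu, 3))
  }, logical(1))))
  # coupled moments feed the previous posterior mean forward
  expect_equal(m2$moments[[2]]$mu, m2$w_tilde[[1]])
  expect_equal(m2$moments[[4]]$mu, m2$w_tilde[[3]])

  expect_error(prior_moments("M3", coupling_state(lu, lc, delta = c(1, 0)),
                             segs), "length H - 1")
  expect_error(prior_moments("M2", coupling_state(lu), segs), "lambda_c")
})

test_that("lambda full conditionals have the derived shapes and rates", {
  hy <- nhdbn_hyper()
  segs <- make_segments(2, H = 4L, Th = 6L, k = 3L)  # k + 1 = 4
  st3 <- coupling_state(2, 0.5, delta = c(1, 0, 1))
  pm <- prior_moments("M3", st3, segs)
  set.seed(9)
  w <- lapply(1:4, function(h) rnorm(4))
  sig2 <- 1.7

  # M1: one factor over all H segments, shape alpha_u + H (k+1) / 2
  c1 <- lambda_conditionals("M1", coupling_state(2), w, pm$w_tilde, sig2, hy)
  expect_equal(unname(c1$lambda_u["shape"]), hy$alpha_u + 8)
  expect_equal(unname(c1$lambda_u["rate"]),
               hy$beta_u + sum(unlist(w)^2) / (2 * sig2))

  # M2: lambda_u from segment 1 only; lambda_c shape alpha_c + (H-1)(k+1)/2
  st2 <- coupling_state(2, 0.5)
  pm2 <- prior_moments("M2", st2, segs)
  c2 <- lambda_conditionals("M2", st2, w, pm2$w_tilde, sig2, hy)
  expect_equal(unname(c2$lambda_u["shape"]), hy$alpha_u + 2)
  expect_equal(unname(c2$lambda_u["rate"]),
               hy$beta_u + sum(w[[1]]^2) / (2 * sig2))
  expect_equal(unname(c2$lambda_c["shape"]), hy$alpha_c + 6)
  Dc2 <- sum(vapply(2:4, function(h) {
    sum((w[[h]] - pm2$w_tilde[[h - 1]])^2)
  }, numeric(1)))
  expect_equal(unname(c2$lambda_c["rate"]), hy$beta_c + Dc2 / (2 * sig2))

  # M3 splits segments by delta; H_c + H_u = H always
  c3 <- lambda_conditionals("M3", st3, w, pm$w_tilde, sig2, hy)
  Hc <- sum(st3$delta)
  Hu <- 1 + sum(1 - st3$delta)
  expect_equal(Hc + Hu, 4)
  expect_equal(unname(c3$lambda_u["shape"]), hy$alpha_u + Hu * 4 / 2)
  expect_equal(unname(c3$lambda_c["shape"]), hy$alpha_c + Hc * 4 / 2)

  # M3 with no coupled segment: lambda_c conditional is its prior
  st0 <- coupling_state(2, 0.5, delta = c(0, 0, 0))
  pm0 <- prior_moments("M3", st0, segs)
  c0 <- lambda_conditionals("M3", st0, w, pm0$w_tilde, sig2, hy)
  expect_equal(unname(c0$lambda_c), c(hy$alpha_c, hy$beta_c))

  # M4: one factor per segment h >= 2 with shape alpha_c + (k+1)/2
  st4 <- coupling_state(2, lambda_h = c(1, 2, 3))
  pm4 <- prior_moments("M4", st4, segs)
  c4 <- lambda_conditionals("M4", st4, w, pm4$w_tilde, sig2, hy)
  expect_length(c4$lambda_h, 3L)
  expect_equal(unname(vapply(c4$lambda_h, `[[`, numeric(1), "shape")),
               rep(hy$alpha_c + 2, 3))
  expect_equal(unname(c4$lambda_h[[2]]["rate"]),
               hy$beta_c + sum((w[[3]] - pm4$w_tilde[[2]])^2) / (2 * sig2))

  # sampling returns a state with all factors positive
  set.seed(10)
  upd <- sample_lambdas("M3", st3, w, pm$w_tilde, sig2, hy)
  expect_gt(upd$lambda_u, 0)
  expect_gt(upd$lambda_c, 0)
})

test_that("coupling-indicator prior matches Gamma arithmetic and integrates p", {
  expect_equal(log_delta_prior(c(1, 0), 1, 1), log(1 / 6))
  expect_equal(log_delta_prior(1, 1, 1), log(1 / 2))
  # independent oracle: numerical integration over the Beta-distributed p
  for (ab in list(c(1, 1), c(2, 5))) {
    delta <- c(1, 1, 0)
    num <- stats::integrate(function(p) {
      stats::dbeta(p, ab[1], ab[2]) *
        p^sum(delta) * (1 - p)^sum(1 - delta)
    }, 0, 1, rel.tol = 1e-10)$value
    expect_equal(log_delta_prior(delta, ab[1], ab[2]), log(num),
                 tolerance = 1e-8)
  }
  # normalization by enumeration for H - 1 = 1..5 indicator slots
  for (m in 1:5) {
    grid <- as.matrix(expand.grid(rep(list(0:1), m)))
    total <- sum(apply(grid, 1, function(d) exp(log_delta_prior(d, 1.3, 0.8))))
    expect_equal(total, 1, tolerance = 1e-12)
  }
})

test_that("collapsed delta updates are exact on symmetric and extreme cases", {
  # symmetric instance: lambda_u = lambda_c and w~_1 = 0 makes both
  # candidate posteriors identical, so P(delta_2 = 1) = 1/2 exactly
  set.seed(14)
  X1 <- cbind(1, rnorm(4))
  segs <- list(list(y = rep(0, 4), X = X1),
               list(y = rnorm(4), X = cbind(1, rnorm(4))))
  st <- coupling_state(lambda_u = 1.5, lambda_c = 1.5, delta = 1L)
  expect_equal(delta_conditional_prob(2, st, segs), 0.5)

  # overwhelming prior mass on uncoupled drives the probability to zero
  hy_unc <- nhdbn_hyper(a = 1, b = 1e6)
  expect_lt(delta_conditional_prob(2, st, segs, hy_unc), 1e-4)

  # identical generating coefficients across two segments favour coupling;
  # the empirical Gibbs frequency agrees with the enumerated probability
  set.seed(15)
  w_true <- c(0.4, 1)
  mk <- function() {
    X <- cbind(1, rnorm(10))
    list(y = drop(X %*% w_true) + rnorm(10, sd = 0.05), X = X)
  }
  segs2 <- list(mk(), mk())
  st2 <- coupling_state(lambda_u = 2, lambda_c = 0.3, delta = 0L)
  p1 <- delta_conditional_prob(2, st2, segs2)
  expect_gt(p1, 0.5)
  set.seed(16)
  freq <- mean(replicate(2000, sample_delta(2, st2, segs2)$delta[1]))
  expect_lt(abs(freq - p1), 3 * sqrt(p1 * (1 - p1) / 2000) + 1e-9)
})

test_that("changepoint prior evaluates and normalizes exactly", {
  expect_equal(log_changepoint_prior(integer(), T = 5, p_cp = 0.1),
               log(0.9^4))
  expect_equal(log_changepoint_prior(c(3, 7), T = 12, p_cp = 0.3),
               2 * log(0.3) + 9 * log(0.7))
  # normalization by enumerating all subsets of positions 1..T-1
  for (T in c(6, 12)) {
    npos <- T - 1
    total <- 0
    for (mask in 0:(2^npos - 1)) {
      tau <- which(bitwAnd(mask, 2^(0:(npos - 1))) > 0)
      total <- total + exp(log_changepoint_prior(tau, T, 0.23))
    }
    expect_equal(total, 1, tolerance = 1e-12)
  }
  # vanishing p concentrates all mass on the empty set
  expect_equal(log_changepoint_prior(integer(), T = 10, p_cp = 1e-12), 0,
               tolerance = 1e-10)
})

test_that("parent-set prior is uniform under the fan-in restriction", {
  expect_identical(log_parent_prior(4, n = 10, fan_in = 3), -Inf)
  expect_equal(exp(-log_parent_prior(0, n = 4, fan_in = 3)), 15)
  # any two admissible sets have prior ratio 1
  expect_equal(log_parent_prior(1, n = 7) - log_parent_prior(3, n = 7), 0)
  expect_equal(log_parent_prior(c(2L, 5L), n = 6), log_parent_prior(2, n = 6))
})
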