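# Cross-checks between the compiled sampler's likelihood path and the R
# reference implementation, determinism contracts, and small-scale
# sampler-correctness checks.

test_that("compiled and R marginal likelihoods agree for every variant", {
  hy <- nhdbn_hyper()
  for (seed in 1:4) {
    set.seed(300 + seed)
    task <- random_task(N = 5L, Tn = 18L, seed = seed)
    pi <- sort(sample(4, 2))
    tau <- c(6L, 12L)
    lu <- rexp(1) + 0.5
    lc <- rexp(1) + 0.2
    lh <- rexp(2) + 0.3
    delta <- sample(0:1, 2, replace = TRUE)
    states <- list(
      M1 = coupling_state(lu),
      M2 = coupling_state(lu, lc),
      M3 = coupling_state(lu, lc, delta = delta),
      M4 = coupling_state(lu, lambda_h = lh)
    )
    for (v in 1:4) {
      variant <- names(states)[v]
      r_val <- model_log_marginal(task, variant, states[[variant]],
                                  parents = pi, tau = tau, hyper = hy)
      c_val <- nhdbn:::cpp_log_marginal(
        task$response, task$covariates, task$valid, as.integer(pi), tau,
        v, lu, lc, if (v == 4) lh else numeric(),
        if (v == 3) as.integer(delta) else integer(), unclass(hy)
      )
      expect_equal(r_val, c_val, tolerance = 1e-10)
    }
  }
})

test_that("chains are reproducible from their seed and count samples", {
  task <- random_task(N = 4L, Tn = 14L, seed = 2)
  cfg <- chain_config(iterations = 400L, thinning = 4L)
  a <- run_chain(task, "M3", config = cfg, seed = 77)
  b <- run_chain(task, "M3", config = cfg, seed = 77)
  expect_identical(a$samples, b$samples)
  d <- run_chain(task, "M3", config = cfg, seed = 78)
  expect_false(identical(a$samples$log_marginal, d$samples$log_marginal))

  expect_equal(n_retained(chain_config(100)), 5L)
  expect_equal(nrow(run_chain(task, "M1",
                              config = chain_config(100), seed = 1)$samples),
               5L)
  # |pi| never exceeds the fan-in; tau stays inside 1..T-1
  expect_true(all(a$samples$n_parents <= 3))
  expect_true(all(unlist(a$samples$tau) >= 1 &
                    unlist(a$samples$tau) < task$T))
})

test_that("fixed changepoints pin the segmentation", {
  task <- random_task(N = 4L, Tn = 20L, seed = 3)
  ch <- run_chain(task, "M3", config = chain_config(300L, thinning = 3L),
                  fixed_changepoints = c(10), seed = 5)
  expect_true(all(vapply(ch$samples$tau, identical, logical(1), 10L)))
  expect_true(all(ch$samples$n_segments == 2L))
  cp <- coupling_probabilities(ch)
  expect_equal(cp$segment, 2L)
  expect_true(cp$prob_coupled >= 0 && cp$prob_coupled <= 1)
})

test_that("coupling indicators recover the generating regime at fixed tau", {
  # two segments, one covariate; coefficients either flip sign (drastic
  # change, should uncouple) or stay identical (should couple)
  gen <- function(flip, seed) {
    set.seed(seed)
    w <- c(0.5, 0.9)
    x <- rnorm(1)
    vals <- matrix(0, 2, 25, dimnames = list(c("Y", "X"), NULL))
    vals[2, ] <- rnorm(25)
    vals[1, 1] <- rnorm(1)
    for (t in 1:24) {
      wh <- if (t <= 12) w else if (flip) -w else w
      vals[1, t + 1] <- wh[1] + wh[2] * vals[2, t] + rnorm(1, sd = 0.05)
    }
    build_regression_task(expression_data(vals), "Y")
  }
  cfg <- chain_config(4000L)
  p_same <- mean(vapply(1:3, function(s) {
    ch <- run_chain(gen(FALSE, s), "M3", config = cfg,
                    fixed_changepoints = 12, seed = s)
    coupling_probabilities(ch)$prob_coupled
  }, numeric(1)))
  p_flip <- mean(vapply(1:3, function(s) {
    ch <- run_chain(gen(TRUE, s), "M3", config = cfg,
                    fixed_changepoints = 12, seed = s)
    coupling_probabilities(ch)$prob_coupled
  }, numeric(1)))
  expect_gt(p_same, 0.5)
  expect_lt(p_flip, 0.5)
})

test_that("a short successive-conditional run preserves the prior (M1)", {
  # reduced version of the joint-distribution check: alternating
  # data-regeneration and one MCMC iteration must leave the prior of
  # (lambda_u, |pi|, H) invariant
  hy <- nhdbn_hyper(alpha_sigma = 2, beta_sigma = 2, p_cp = 0.2)
  set.seed(41)
  Xc <- matrix(rnorm(8 * 2), 8, 2)
  tr <- nhdbn:::cpp_geweke(Xc, 8L, 1L, unclass(hy), 20000L, 1L, FALSE,
                           integer())
  expect_lt(abs(mean(tr[, "inv_lambda_u"]) - 10),
            4 * batch_means_se(tr[, "inv_lambda_u"]))
  expect_lt(abs(mean(tr[, "pi_size"]) - 1),
            4 * batch_means_se(tr[, "pi_size"]))
  expect_lt(abs(mean(tr[, "H"]) - (1 + 7 * 0.2)),
            4 * batch_means_se(tr[, "H"]))
})

test_that("network inference is node-order invariant and propagates names", {
  sim <- generate_study2(m = 5, seed = 88)
  cfg <- chain_config(800L, thinning = 4L)
  fit <- infer_network(sim$data, "M1", config = cfg, seed = 9)
  # permuting the input rows permutes the scores, nothing else
  perm_data <- expression_data(sim$data$values[c(3, 1, 5, 2, 4), ])
  fit_p <- infer_network(perm_data, "M1", config = cfg, seed = 9)
  joined <- merge(as.data.frame(fit$scores), as.data.frame(fit_p$scores),
                  by = c("parent", "child"))
  expect_equal(joined$score.x, joined$score.y)
  # each chain excludes its own target from the candidates
  for (nm in names(fit$chains)) {
    expect_false(nm %in% fit$chains[[nm]]$candidates)
  }
  expect_equal(nrow(fit$scores), 5 * 4)
})
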