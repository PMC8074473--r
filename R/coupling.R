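#' Model hyperparameters for the four NH-DBN variants
#'
#' Collects the fixed hyperparameters shared by the model variants.  The
#' defaults are the standard uninformative settings for this model family:
#' `sigma^-2 ~ GAM(nu, nu)` with `nu = 0.005`,
#' `lambda_u^-1 ~ GAM(2, 0.2)` (signal-to-noise prior of the uncoupled
#' coefficient prior), `lambda_c^-1 ~ GAM(3, 3)` (coupling-strength
#' prior), a flat `BETA(1, 1)` hyperprior on the coupling probability of
#' the partially coupled model, changepoint-distance hyperparameter
#' `p_cp = 0.05`, and a fan-in restriction of 3 parents.
#'
#' @param alpha_sigma,beta_sigma Inverse-Gamma prior on the noise variance.
#' @param alpha_u,beta_u Inverse-Gamma prior on the uncoupled variance
#'   factor `lambda_u`.
#' @param alpha_c,beta_c Inverse-Gamma prior on the coupling variance
#'   factor(s) `lambda_c` / `lambda_h`.
#' @param a,b Beta hyperprior on the coupling probability `p` of the
#'   coupling indicators.
#' @param p_cp Success probability of the geometric prior on the distance
#'   between changepoints, in `(0, 1)`.
#' @param fan_in Maximum parent-set size with non-zero prior mass.
#' @return A list of class `nhdbn_hyper`.
#' @export
nhdbn_hyper <- function(alpha_sigma = 0.005, beta_sigma = 0.005,
                        alpha_u = 2, beta_u = 0.2,
                        alpha_c = 3, beta_c = 3,
                        a = 1, b = 1,
                        p_cp = 0.05, fan_in = 3L) {
  stopifnot(alpha_sigma > 0, beta_sigma > 0, alpha_u > 0, beta_u > 0,
            alpha_c > 0, beta_c > 0, a > 0, b > 0,
            p_cp > 0, p_cp < 1, fan_in >= 1)
  structure(
    list(alpha_sigma = alpha_sigma, beta_sigma = beta_sigma,
         alpha_u = alpha_u, beta_u = beta_u,
         alpha_c = alpha_c, beta_c = beta_c,
         a = a, b = b, p_cp = p_cp, fan_in = as.integer(fan_in)),
    class = "nhdbn_hyper"
  )
}

#' @rdname nhdbn_hyper
#' @param x An `nhdbn_hyper` object.
#' @export
noise_of <- function(x) {
  stopifnot(inherits(x, "nhdbn_hyper"))
  noise_hyper(x$alpha_sigma, x$beta_sigma)
}

model_variants <- c("M1", "M2", "M3", "M4")

check_variant <- function(variant) {
  variant <- match.arg(variant, model_variants)
  variant
}

#' Continuous/discrete coupling state of one model variant
#'
#' Bundles the variance factors and coupling indicators a variant needs:
#' M1 uses `lambda_u` only; M2 adds the shared coupling factor
#' `lambda_c`; M3 adds binary indicators `delta[h]` for segments
#' `h = 2..H` (segment 1 is uncoupled by definition); M4 replaces the
#' shared `lambda_c` by segment-specific factors `lambda_h[h]`,
#' `h = 2..H`.
#'
#' @param lambda_u Positive uncoupled (SNR) variance factor.
#' @param lambda_c Positive shared coupling variance factor (M2/M3).
#' @param lambda_h Numeric vector of positive segment-specific coupling
#'   factors for segments `2..H` (M4); length `H - 1`.
#' @param delta Binary vector of coupling indicators for segments `2..H`
#'   (M3); length `H - 1`.
#' @return A list of class `nhdbn_state`.
#' @export
coupling_state <- function(lambda_u, lambda_c = NULL, lambda_h = NULL,
                           delta = NULL) {
  stopifnot(lambda_u > 0)
  if (!is.null(lambda_c)) stopifnot(lambda_c > 0)
  if (!is.null(lambda_h)) stopifnot(all(lambda_h > 0))
  if (!is.null(delta)) stopifnot(all(delta %in% c(0L, 1L)))
  structure(
    list(lambda_u = lambda_u, lambda_c = lambda_c,
         lambda_h = lambda_h, delta = as.integer(delta)),
    class = "nhdbn_state"
  )
}

check_state <- function(variant, state, H) {
  stopifnot(inherits(state, "nhdbn_state"))
  if (variant %in% c("M2", "M3") && is.null(state$lambda_c)) {
    stop(variant, " requires lambda_c", call. = FALSE)
  }
  if (variant == "M3" && length(state$delta) != H - 1L) {
    stop("M3 requires delta of length H - 1 = ", H - 1L, call. = FALSE)
  }
  if (variant == "M4" && length(state$lambda_h) != H - 1L) {
    stop("M4 requires lambda_h of length H - 1 = ", H - 1L, call. = FALSE)
  }
  invisible(state)
}

# Per-segment (lambda, coupled?) scalars for a variant; segment 1 is
# always (lambda_u, uncoupled).
segment_lambda <- function(variant, state, h) {
  if (h == 1L) return(list(lambda = state$lambda_u, coupled = FALSE))
  switch(variant,
    M1 = list(lambda = state$lambda_u, coupled = FALSE),
    M2 = list(lambda = state$lambda_c, coupled = TRUE),
    M3 = if (state$delta[h - 1L] == 1L) {
      list(lambda = state$lambda_c, coupled = TRUE)
    } else {
      list(lambda = state$lambda_u, coupled = FALSE)
    },
    M4 = list(lambda = state$lambda_h[h - 1L], coupled = TRUE)
  )
}

#' Per-segment prior moments under a model variant
#'
#' Maps the coupling state to the generic prior moments `(mu_h, Sigma_h)`
#' of every segment.  Uncoupled segments get a zero prior mean with
#' covariance factor `lambda_u I`; coupled segments get the posterior
#' expectation of the previous segment's coefficients as prior mean
#' (`w~_{h-1}`, computed by a forward recursion with `w~_0 = 0` and each
#' `w~_{h-1}` treated as fixed when used for segment `h`) with covariance
#' factor `lambda_c I` (M2, M3 with `delta_h = 1`) or `lambda_h I` (M4).
#'
#' @param variant One of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @param state A [coupling_state()] consistent with the variant.
#' @param segments Segment list from [segmentize()] (the recursion needs
#'   the data).
#' @return A list with `moments` (per-segment lists of `mu`, `Sigma`) and
#'   `w_tilde` (per-segment posterior-mean vectors `w~_1 .. w~_H`).
#' @export
prior_moments <- function(variant, state, segments) {
  variant <- check_variant(variant)
  H <- length(segments)
  check_state(variant, state, H)
  k1 <- ncol(segments[[1L]]$X)
  moments <- vector("list", H)
  w_tilde <- vector("list", H)
  w_prev <- rep(0, k1)
  for (h in seq_len(H)) {
    sl <- segment_lambda(variant, state, h)
    mu <- if (sl$coupled) w_prev else rep(0, k1)
    Sigma <- diag(sl$lambda, k1)
    moments[[h]] <- list(mu = mu, Sigma = Sigma)
    w_prev <- posterior_mean_weights(segments[[h]], mu, Sigma)
    w_tilde[[h]] <- w_prev
  }
  list(moments = moments, w_tilde = w_tilde)
}

#' Log marginal likelihood of a task under one model variant
#'
#' Convenience wrapper: segmentizes the task for a parent set and
#' changepoint set, derives the variant's prior moments and evaluates the
#' closed-form marginal likelihood.
#'
#' @inheritParams prior_moments
#' @param task A [build_regression_task()] object.
#' @param parents Parent set (indices or names of covariate columns).
#' @param tau Changepoint set.
#' @param hyper A [nhdbn_hyper()] object.
#' @param min_seg_len Minimum valid observations per segment.
#' @return Log marginal likelihood.
#' @export
model_log_marginal <- function(task, variant, state, parents = integer(),
                               tau = integer(), hyper = nhdbn_hyper(),
                               min_seg_len = 2L) {
  segments <- segmentize(task, tau = tau, parents = parents,
                         min_seg_len = min_seg_len)
  pm <- prior_moments(variant, state, segments)
  log_marginal_likelihood(segments, pm$moments, noise_of(hyper))
}

#' Gamma full-conditional parameters of the variance factors
#'
#' Returns the shape/rate pairs of the inverse variance factors'
#' full conditional distributions given freshly drawn coefficient vectors:
#' for every factor the shape grows by `(k+1)/2` per segment it governs
#' and the rate by `sigma^-2/2` times the squared distance between the
#' segment coefficients and their prior mean.  Factors governing no
#' segment fall back to their prior.
#'
#' @inheritParams prior_moments
#' @param weights List of per-segment coefficient vectors `w_1..w_H`.
#' @param w_tilde List of per-segment posterior-mean vectors (from
#'   [prior_moments()] under the state the weights were drawn with).
#' @param sigma2 Current noise variance.
#' @param hyper A [nhdbn_hyper()] object.
#' @return Named list of `c(shape, rate)` pairs: always `lambda_u`;
#'   `lambda_c` for M2/M3; `lambda_h` (a list over segments `2..H`) for
#'   M4.
#' @export
lambda_conditionals <- function(variant, state, weights, w_tilde, sigma2,
                                hyper = nhdbn_hyper()) {
  variant <- check_variant(variant)
  H <- length(weights)
  check_state(variant, state, H)
  k1 <- length(weights[[1L]])
  wt_prev <- c(list(rep(0, k1)), w_tilde[-H])  # w~_{h-1}, with w~_0 = 0
  sq <- function(v) sum(v * v)
  out <- list()
  if (variant == "M1") {
    D2 <- sum(vapply(weights, sq, numeric(1)))
    out$lambda_u <- c(shape = hyper$alpha_u + H * k1 / 2,
                      rate = hyper$beta_u + D2 / (2 * sigma2))
  } else {
    coupled <- vapply(seq_len(H), function(h) {
      segment_lambda(variant, state, h)$coupled
    }, logical(1))
    Du2 <- sum(vapply(which(!coupled), function(h) sq(weights[[h]]),
                      numeric(1)))
    out$lambda_u <- c(shape = hyper$alpha_u + sum(!coupled) * k1 / 2,
                      rate = hyper$beta_u + Du2 / (2 * sigma2))
    if (variant %in% c("M2", "M3")) {
      Dc2 <- sum(vapply(which(coupled), function(h) {
        sq(weights[[h]] - wt_prev[[h]])
      }, numeric(1)))
      out$lambda_c <- c(shape = hyper$alpha_c + sum(coupled) * k1 / 2,
                        rate = hyper$beta_c + Dc2 / (2 * sigma2))
    } else {  # M4: one factor per segment h >= 2
      out$lambda_h <- lapply(seq_len(H)[-1L], function(h) {
        c(shape = hyper$alpha_c + k1 / 2,
          rate = hyper$beta_c + sq(weights[[h]] - wt_prev[[h]]) / (2 * sigma2))
      })
    }
  }
  out
}

#' Draw the variance factors from their full conditionals
#'
#' Samples each inverse variance factor from the Gamma distribution given
#' by [lambda_conditionals()] and returns the updated state.
#'
#' @inheritParams lambda_conditionals
#' @return An updated [coupling_state()].
#' @export
sample_lambdas <- function(variant, state, weights, w_tilde, sigma2,
                           hyper = nhdbn_hyper()) {
  cond <- lambda_conditionals(variant, state, weights, w_tilde, sigma2,
                              hyper)
  state$lambda_u <- 1 / rgamma(1, shape = cond$lambda_u["shape"],
                               rate = cond$lambda_u["rate"])
  if (!is.null(cond$lambda_c)) {
    state$lambda_c <- 1 / rgamma(1, shape = cond$lambda_c["shape"],
                                 rate = cond$lambda_c["rate"])
  }
  if (!is.null(cond$lambda_h)) {
    state$lambda_h <- vapply(cond$lambda_h, function(p) {
      1 / rgamma(1, shape = p["shape"], rate = p["rate"])
    }, numeric(1))
  }
  state
}

#' Log marginal prior of the coupling-indicator vector
#'
#' With `delta_h ~ BER(p)` and `p ~ BETA(a, b)` integrated out,
#' \deqn{p(\delta_2..\delta_H) =
#'   \frac{\Gamma(a+b)}{\Gamma(a)\Gamma(b)}
#'   \frac{\Gamma(a + \sum\delta_h)\,\Gamma(b + \sum(1-\delta_h))}
#'        {\Gamma(a + b + H - 1)}.}
#'
#' @param delta Binary vector for segments `2..H` (possibly empty).
#' @param a,b Beta hyperparameters.
#' @return Log prior mass.
#' @examples
#' exp(log_delta_prior(c(1, 0), 1, 1))  # 1/6
#' @export
log_delta_prior <- function(delta, a = 1, b = 1) {
  stopifnot(all(delta %in% c(0, 1)), a > 0, b > 0)
  s <- sum(delta)
  m <- length(delta)
  lgamma(a + b) - lgamma(a) - lgamma(b) +
    lgamma(a + s) + lgamma(b + m - s) - lgamma(a + b + m)
}

#' Collapsed full-conditional probability of one coupling indicator
#'
#' For the partially coupled model, the success probability of
#' `delta_k | rest` with the coefficient vectors, the noise variance and
#' the coupling probability integrated out.  Both candidate values re-run
#' the full posterior-mean forward recursion, since `delta_k` enters the
#' prior means of all downstream segments.
#'
#' @param k Segment index, `2 <= k <= H`.
#' @param state A [coupling_state()] for M3.
#' @param segments Segment list from [segmentize()].
#' @param hyper A [nhdbn_hyper()] object.
#' @return `P(delta_k = 1 | ...)` in `[0, 1]`.
#' @export
delta_conditional_prob <- function(k, state, segments,
                                   hyper = nhdbn_hyper()) {
  H <- length(segments)
  stopifnot(k >= 2L, k <= H)
  noise <- noise_of(hyper)
  lp <- vapply(c(0L, 1L), function(val) {
    st <- state
    st$delta[k - 1L] <- val
    pm <- prior_moments("M3", st, segments)
    log_marginal_likelihood(segments, pm$moments, noise) +
      log_delta_prior(st$delta, hyper$a, hyper$b)
  }, numeric(1))
  1 / (1 + exp(lp[1L] - lp[2L]))
}

#' Draw one coupling indicator by collapsed Gibbs sampling
#'
#' @inheritParams delta_conditional_prob
#' @return An updated [coupling_state()] with `delta[k-1]` redrawn.
#' @export
sample_delta <- function(k, state, segments, hyper = nhdbn_hyper()) {
  p1 <- delta_conditional_prob(k, state, segments, hyper)
  state$delta[k - 1L] <- as.integer(runif(1) < p1)
  state
}

#' Log prior of a changepoint set
#'
#' The distance between changepoints is geometrically distributed with
#' hyperparameter `p`, which collapses to
#' `p(tau) = p^(H-1) (1-p)^((T-1)-(H-1))` -- equivalently, each of the
#' `T - 1` admissible positions carries an independent Bernoulli(`p`)
#' changepoint.
#'
#' @param tau Changepoint set (sorted integers in `1..T-1`).
#' @param T Number of observations.
#' @param p_cp Hyperparameter in `(0, 1)`.
#' @return Log prior mass.
#' @examples
#' exp(log_changepoint_prior(integer(), T = 5, p_cp = 0.1))  # 0.9^4
#' @export
log_changepoint_prior <- function(tau, T, p_cp) {
  stopifnot(p_cp > 0, p_cp < 1, T >= 2)
  m <- length(tau)
  m * log(p_cp) + ((T - 1) - m) * log1p(-p_cp)
}

#' Log prior of a parent set under the fan-in restriction
#'
#' Parent sets with at most `fan_in` covariates are equally likely a
#' priori; larger sets have zero mass.  The normalizer counts all
#' admissible subsets of the `n` candidates.
#'
#' @param size Parent-set size `|pi|` (or a parent vector, whose length is
#'   used).
#' @param n Number of candidate covariates.
#' @param fan_in Maximum admissible size.
#' @return Log prior mass (`-Inf` above the fan-in).
#' @examples
#' log_parent_prior(4, n = 10, fan_in = 3)  # -Inf
#' @export
log_parent_prior <- function(size, n, fan_in = 3L) {
  if (length(size) != 1L || !is.numeric(size)) size <- length(size)
  if (size > fan_in) return(-Inf)
  -log(sum(choose(n, 0:min(fan_in, n))))
}
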