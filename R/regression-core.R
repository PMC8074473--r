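#' Noise-variance hyperparameters
#'
#' The shared noise variance sigma^2 carries an inverse-Gamma prior:
#' `sigma^-2 ~ GAM(alpha_sigma, beta_sigma)`.  The default
#' `alpha_sigma = beta_sigma = 0.005` is the standard uninformative
#' setting for this model family.
#'
#' @param alpha_sigma,beta_sigma Positive shape and rate.
#' @return A list of class `nhdbn_noise`.
#' @export
noise_hyper <- function(alpha_sigma = 0.005, beta_sigma = 0.005) {
  stopifnot(alpha_sigma > 0, beta_sigma > 0)
  structure(list(alpha_sigma = alpha_sigma, beta_sigma = beta_sigma),
            class = "nhdbn_noise")
}

# Per-segment sufficient statistics under prior moments (mu, Sigma):
#   A       = Sigma^-1 + X'X              (posterior precision / sigma^-2)
#   postmean= A^-1 (Sigma^-1 mu + X'y)    (posterior mean of w)
#   logdetC = log det(I + X Sigma X')     (via det lemma, small matrix)
#   quad    = (y - X mu)' C^-1 (y - X mu) (via Woodbury, small matrix)
# All factorizations act on the (k+1)x(k+1) inner matrix, never on the
# T_h x T_h form.
seg_stats <- function(seg, mu, Sigma) {
  X <- seg$X
  y <- seg$y
  k1 <- ncol(X)
  stopifnot(length(mu) == k1, all(dim(Sigma) == k1))
  cS <- chol(Sigma)
  Sinv <- chol2inv(cS)
  A <- Sinv + crossprod(X)
  cA <- chol(A)
  Ainv <- chol2inv(cA)
  postmean <- drop(Ainv %*% (Sinv %*% mu + crossprod(X, y)))
  r <- y - drop(X %*% mu)
  b <- crossprod(X, r)
  list(
    A = A, cholA = cA, Ainv = Ainv, postmean = postmean,
    logdetC = 2 * sum(log(diag(cS))) + 2 * sum(log(diag(cA))),
    quad = max(0, sum(r * r) - drop(crossprod(b, Ainv %*% b))),
    Th = length(y)
  )
}

#' Marginal covariance matrix of one segment
#'
#' Returns `C_h = I + X_h Sigma_h X_h'`, the covariance (up to the factor
#' sigma^2) of the segment response once the coefficient vector is
#' integrated out.  Formed explicitly; intended for small instances and
#' cross-checks -- the likelihood code itself only ever factorizes the
#' `(k+1)`-by-`(k+1)` inner matrix.
#'
#' @param X Design matrix `T_h x (k+1)`.
#' @param Sigma Positive-definite prior covariance factor `(k+1) x (k+1)`.
#' @return Symmetric `T_h x T_h` matrix with eigenvalues `>= 1`.
#' @examples
#' cov_matrix_C(matrix(c(1, 2), 1), diag(2))  # 6
#' @export
cov_matrix_C <- function(X, Sigma) {
  X <- as.matrix(X)
  Sigma <- as.matrix(Sigma)
  if (ncol(X) != nrow(Sigma)) stop("dimension mismatch", call. = FALSE)
  diag(nrow(X)) + X %*% Sigma %*% t(X)
}

# Normalize a `moments` argument: a list with one (mu, Sigma) pair per
# segment.
check_moments <- function(segments, moments) {
  stopifnot(is.list(segments), is.list(moments),
            length(moments) == length(segments))
  moments
}

#' Total Mahalanobis residual of a segmented regression
#'
#' `Delta^2 = sum_h (y_h - X_h mu_h)' C_h^-1 (y_h - X_h mu_h)` with
#' `C_h = I + X_h Sigma_h X_h'`.  Computed through a Cholesky
#' factorization of the inner `(k+1)`-dimensional matrix (Woodbury), never
#' by explicit inversion of `C_h`.
#'
#' @param segments List of segments as returned by [segmentize()].
#' @param moments List (one entry per segment) of lists with elements
#'   `mu` (prior mean vector) and `Sigma` (prior covariance factor).
#' @return Non-negative scalar.
#' @export
delta_squared <- function(segments, moments) {
  moments <- check_moments(segments, moments)
  sum(vapply(seq_along(segments), function(h) {
    seg_stats(segments[[h]], moments[[h]]$mu, moments[[h]]$Sigma)$quad
  }, numeric(1)))
}

#' Log marginal likelihood of the segmented Gaussian regression
#'
#' The coefficient vectors of all segments and the shared noise variance
#' are integrated out analytically:
#' \deqn{\log p(y|\theta) = \log\Gamma(T/2+\alpha) - \log\Gamma(\alpha)
#'   - (T/2)\log\pi + \alpha\log(2\beta)
#'   - \tfrac12 \sum_h \log\det C_h - (T/2+\alpha)\log(2\beta+\Delta^2)}
#' where `T` is the total number of observations across segments.
#'
#' @inheritParams delta_squared
#' @param noise A [noise_hyper()] object.
#' @return Log marginal likelihood (finite for finite inputs).
#' @export
log_marginal_likelihood <- function(segments, moments, noise = noise_hyper()) {
  stopifnot(inherits(noise, "nhdbn_noise"))
  moments <- check_moments(segments, moments)
  stats <- lapply(seq_along(segments), function(h) {
    seg_stats(segments[[h]], moments[[h]]$mu, moments[[h]]$Sigma)
  })
  Tn <- sum(vapply(stats, `[[`, numeric(1), "Th"))
  if (Tn < 1) stop("empty segmentation", call. = FALSE)
  d2 <- sum(vapply(stats, `[[`, numeric(1), "quad"))
  ldC <- sum(vapply(stats, `[[`, numeric(1), "logdetC"))
  a <- noise$alpha_sigma
  b <- noise$beta_sigma
  lgamma(Tn / 2 + a) - lgamma(a) - (Tn / 2) * log(pi) + a * log(2 * b) -
    ldC / 2 - (Tn / 2 + a) * log(2 * b + d2)
}

#' Draw the noise variance from its collapsed full conditional
#'
#' With the coefficient vectors integrated out,
#' `sigma^-2 | y, theta ~ GAM(alpha_sigma + T/2, beta_sigma + Delta^2/2)`.
#'
#' @inheritParams log_marginal_likelihood
#' @return A positive draw of `sigma^2`.
#' @export
sample_sigma2 <- function(segments, moments, noise = noise_hyper()) {
  moments <- check_moments(segments, moments)
  Tn <- sum(vapply(segments, function(s) length(s$y), numeric(1)))
  d2 <- delta_squared(segments, moments)
  1 / rgamma(1, shape = noise$alpha_sigma + Tn / 2,
             rate = noise$beta_sigma + d2 / 2)
}

#' Posterior mean of one segment's coefficient vector
#'
#' `[Sigma^-1 + X'X]^-1 (Sigma^-1 mu + X'y)`; deterministic.  This is the
#' quantity fed forward as the next segment's prior mean under sequential
#' coupling.
#'
#' @param seg One segment (`y`, `X`) as produced by [segmentize()].
#' @param mu,Sigma Prior moments of the coefficient vector.
#' @return Numeric vector of length `k + 1`.
#' @export
posterior_mean_weights <- function(seg, mu, Sigma) {
  seg_stats(seg, mu, Sigma)$postmean
}

#' Draw one segment's coefficient vector from its full conditional
#'
#' `w | y, sigma^2 ~ N(m, sigma^2 [Sigma^-1 + X'X]^-1)` with `m` the
#' [posterior_mean_weights()].
#'
#' @inheritParams posterior_mean_weights
#' @param sigma2 Current noise variance (positive).
#' @return Numeric vector of length `k + 1`.
#' @export
sample_weights <- function(seg, sigma2, mu, Sigma) {
  stopifnot(sigma2 > 0)
  st <- seg_stats(seg, mu, Sigma)
  z <- rnorm(length(st$postmean))
  # cov = sigma2 * A^-1 with A = R'R  =>  draw = m + sqrt(sigma2) R^-1 z
  st$postmean + sqrt(sigma2) * backsolve(st$cholA, z)
}
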