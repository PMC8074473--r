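# Independent oracles used across the suite.  Everything here is
# deliberately brute force: dense linear algebra on the T_h x T_h
# covariance, exhaustive enumeration, or grid quadrature -- never the
# package's own Woodbury/closed-form path.

# Delta^2 through the explicit T_h x T_h inverse.
dense_delta_squared <- function(segments, moments) {
  sum(vapply(seq_along(segments), function(h) {
    X <- segments[[h]]$X
    y <- segments[[h]]$y
    mu <- moments[[h]]$mu
    C <- diag(nrow(X)) + X %*% moments[[h]]$Sigma %*% t(X)
    r <- y - drop(X %*% mu)
    drop(t(r) %*% solve(C) %*% r)
  }, numeric(1)))
}

# log det C_h through the explicit T_h x T_h determinant.
dense_logdet_C <- function(seg, Sigma) {
  C <- diag(nrow(seg$X)) + seg$X %*% Sigma %*% t(seg$X)
  as.numeric(determinant(C, logarithm = TRUE)$modulus)
}

# Closed-form limit of the marginal likelihood as the prior variance
# vanishes: w_h pinned at mu_h, sigma^2 still integrated out, i.e. a
# scaled multivariate t evaluation.
pinned_weights_logml <- function(segments, moments, noise) {
  rss <- sum(vapply(seq_along(segments), function(h) {
    r <- segments[[h]]$y - drop(segments[[h]]$X %*% moments[[h]]$mu)
    sum(r * r)
  }, numeric(1)))
  Tn <- sum(vapply(segments, function(s) length(s$y), numeric(1)))
  a <- noise$alpha_sigma
  b <- noise$beta_sigma
  lgamma(Tn / 2 + a) - lgamma(a) - (Tn / 2) * log(pi) + a * log(2 * b) -
    (Tn / 2 + a) * log(2 * b + rss)
}

# Brute-force grid quadrature of the full marginal likelihood
#   p(y) = int p(sigma^2) prod_h int N(y_h | X_h w_h, sigma^2 I)
#                                 N(w_h | mu_h, sigma^2 Sigma_h) dw_h dsigma^2
# with the substitution w = sqrt(sigma^2) u per segment, so a fixed u-grid
# covers both the prior and the likelihood at every noise level.
# Feasible for T <= 4 and k <= 1 (u-grids of dimension <= 2).
quadrature_logml <- function(segments, moments, noise,
                             n_sigma = 400L, n_w = 401L, ulim = 30) {
  a <- noise$alpha_sigma
  b <- noise$beta_sigma
  grids <- lapply(seq_along(segments), function(h) {
    X <- segments[[h]]$X
    y <- segments[[h]]$y
    mu <- moments[[h]]$mu
    Sinv <- solve(moments[[h]]$Sigma)
    k1 <- ncol(X)
    g <- seq(-ulim, ulim, length.out = n_w)
    U <- t(as.matrix(expand.grid(rep(list(g), k1))))  # k1 x n_grid
    XtX <- crossprod(X)
    list(
      q0 = colSums(U * (XtX %*% U)),        # u' X'X u
      q1 = drop(crossprod(crossprod(X, y), U)),  # u' X'y
      p0 = colSums(U * (Sinv %*% U)),       # u' Sinv u
      p1 = drop(t(mu) %*% Sinv %*% U),      # mu' Sinv u
      p2 = drop(t(mu) %*% Sinv %*% mu),
      yy = sum(y * y), Th = nrow(X), k1 = k1,
      logdetS = as.numeric(determinant(moments[[h]]$Sigma)$modulus),
      log_du = k1 * log(g[2] - g[1])
    )
  })
  logsumexp <- function(v) {
    m <- max(v)
    m + log(sum(exp(v - m)))
  }
  qs <- 1 / qgamma(c(1e-9, 1 - 1e-9), shape = a, rate = b)
  ls_grid <- seq(log(min(qs)), log(max(qs)), length.out = n_sigma)
  s_grid <- exp(ls_grid)
  logf <- vapply(s_grid, function(s) {
    # inverse-gamma density of sigma^2
    lp <- dgamma(1 / s, shape = a, rate = b, log = TRUE) - 2 * log(s)
    for (gr in grids) {
      li <- -(gr$Th + gr$k1) / 2 * log(2 * pi * s) + gr$k1 / 2 * log(s) -
        gr$logdetS / 2 - gr$yy / (2 * s) + gr$q1 / sqrt(s) - gr$q0 / 2 -
        gr$p0 / 2 + gr$p1 / sqrt(s) - gr$p2 / (2 * s)
      lp <- lp + logsumexp(li) + gr$log_du
    }
    lp
  }, numeric(1))
  # trapezoid in log sigma^2 (Jacobian s)
  vals <- logf + log(s_grid)
  m <- max(vals)
  m + log(sum(diff(ls_grid) *
                (exp(vals[-1L] - m) + exp(vals[-n_sigma] - m)) / 2))
}

# Exhaustive precision-recall AUC: enumerate every threshold placement
# between consecutive distinct scores and integrate the resulting
# (recall, precision) polyline with the same left-endpoint convention.
brute_force_pr_auc <- function(scores, truth_edges) {
  keys <- paste(scores$parent, scores$child)
  truth_keys <- paste(truth_edges$parent, truth_edges$child)
  M <- length(truth_keys)
  ord <- order(scores$score, decreasing = TRUE)
  sc <- scores$score[ord]
  is_true <- keys[ord] %in% truth_keys
  pts <- NULL
  for (xi in unique(c(sc, min(sc) - 1))) {
    sel <- sc > xi
    if (!any(sel)) next
    tp <- sum(is_true & sel)
    pts <- rbind(pts, c(tp / M, tp / sum(sel)))
  }
  pts <- pts[order(pts[, 1L]), , drop = FALSE]
  if (nrow(pts) == 1L) return(pts[1L, 2L] * pts[1L, 1L])
  r <- c(0, pts[, 1L])
  p <- c(pts[1L, 2L], pts[, 2L])
  sum(diff(r) * (head(p, -1L) + p[-1L]) / 2)
}

# Random small regression task for property tests.
random_task <- function(N = 4L, Tn = 12L, seed = 1L) {
  local({
    d <- nhdbn::expression_data(
      matrix(rnorm(N * (Tn + 1L)), N, Tn + 1L,
             dimnames = list(paste0("G", seq_len(N)), NULL))
    )
    nhdbn::build_regression_task(d, 1L)
  })
}

# Random segments + free moments for generic-core property tests.
random_segments <- function(H = 2L, Th = 4L, k = 1L) {
  lapply(seq_len(H), function(h) {
    list(y = rnorm(Th), X = cbind(1, matrix(rnorm(Th * k), Th, k)))
  })
}

random_moments <- function(segments) {
  lapply(segments, function(s) {
    k1 <- ncol(s$X)
    A <- matrix(rnorm(k1 * k1), k1)
    list(mu = rnorm(k1), Sigma = crossprod(A) + diag(k1))
  })
}

withr_local_file <- function(name) {
  file.path(tempdir(), paste0(sample.int(1e8, 1), "-", name))
}

batch_means_se <- function(x, n_batches = 100L) {
  n <- (length(x) %/% n_batches) * n_batches
  bm <- colMeans(matrix(x[seq_len(n)], ncol = n_batches))
  stats::sd(bm) / sqrt(n_batches)
}
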