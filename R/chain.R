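#' MCMC chain configuration
#'
#' Defaults follow the standard protocol for this model family:
#' `V = 100000` iterations, a 50% burn-in and thinning by 10, which
#' retains `W = floor((V - burn_in) / thinning)` posterior samples (5000
#' at the defaults).
#'
#' @param iterations Total RJMCMC iterations `V`.
#' @param burn_in_fraction Fraction of iterations discarded as burn-in.
#' @param thinning Keep every `thinning`-th state after burn-in.
#' @param min_seg_len Minimum number of valid observations per segment;
#'   proposals violating it are rejected.
#' @return A list of class `nhdbn_config`.
#' @export
chain_config <- function(iterations = 100000L, burn_in_fraction = 0.5,
                         thinning = 10L, min_seg_len = 2L) {
  stopifnot(iterations >= thinning, burn_in_fraction >= 0,
            burn_in_fraction < 1, thinning >= 1, min_seg_len >= 1)
  structure(
    list(iterations = as.integer(iterations),
         burn_in_fraction = burn_in_fraction,
         thinning = as.integer(thinning),
         min_seg_len = as.integer(min_seg_len)),
    class = "nhdbn_config"
  )
}

#' Number of retained posterior samples under a configuration
#'
#' `W = floor((V - floor(burn_in_fraction * V)) / thinning)`.
#'
#' @param config A [chain_config()] object.
#' @return Integer sample count.
#' @examples
#' n_retained(chain_config())          # 5000
#' n_retained(chain_config(100))       # 5
#' @export
n_retained <- function(config) {
  stopifnot(inherits(config, "nhdbn_config"))
  burn <- floor(config$burn_in_fraction * config$iterations)
  as.integer((config$iterations - burn) %/% config$thinning)
}

#' Run one reversible-jump MCMC chain for a single target node
#'
#' Each iteration performs a Gibbs sweep over the continuous/discrete
#' model parameters, one Metropolis-Hastings move on the parent set
#' (addition / removal / exchange) and one reversible-jump move on the
#' changepoint set (birth / death / re-allocation).  Supplying
#' `fixed_changepoints` pins the segmentation and disables changepoint
#' moves.
#'
#' @param task A [build_regression_task()] object.
#' @param model Model variant: `"M1"` (uncoupled), `"M2"` (coupled),
#'   `"M3"` (partially coupled, the default) or `"M4"` (generalized
#'   coupled).
#' @param hyper A [nhdbn_hyper()] object.
#' @param config A [chain_config()] object.
#' @param fixed_changepoints Optional integer vector of changepoints to
#'   hold fixed (disables changepoint moves).
#' @param seed Optional integer seed; the caller's RNG state is restored
#'   afterwards.  `NULL` continues the current RNG stream.
#' @return An object of class `nhdbn_chain`: a list with a `samples`
#'   tibble (one row per retained draw: `draw`, `log_marginal`,
#'   `n_parents`, list-columns `parents`, `tau`, `delta`, `lambda_h`, and
#'   `lambda_u`, `lambda_c`, `n_segments`) plus metadata and acceptance
#'   counts.
#' @export
run_chain <- function(task, model = "M3", hyper = nhdbn_hyper(),
                      config = chain_config(), fixed_changepoints = NULL,
                      seed = NULL) {
  stopifnot(inherits(task, "nhdbn_task"), inherits(hyper, "nhdbn_hyper"),
            inherits(config, "nhdbn_config"))
  model <- check_variant(model)
  variant <- match(model, model_variants)
  fix_tau <- !is.null(fixed_changepoints)
  init_tau <- if (fix_tau) as.integer(sort(fixed_changepoints)) else integer()
  if (fix_tau) {
    # validates range and min_seg_len up front
    invisible(segmentize(task, tau = init_tau,
                         min_seg_len = config$min_seg_len))
  }
  raw <- local_seed(seed, cpp_run_chain(
    task$response, task$covariates, task$valid,
    variant, unclass(hyper),
    config$iterations, config$burn_in_fraction, config$thinning,
    fix_tau, init_tau, config$min_seg_len, TRUE
  ))
  cov_names <- colnames(task$covariates)
  W <- length(raw$log_marginal)
  samples <- tibble::tibble(
    draw = seq_len(W),
    log_marginal = raw$log_marginal,
    n_parents = vapply(raw$pi, length, integer(1)),
    parents = lapply(raw$pi, function(ix) cov_names[ix]),
    tau = raw$tau,
    n_segments = vapply(raw$tau, length, integer(1)) + 1L,
    delta = raw$delta,
    lambda_u = raw$lambda_u,
    lambda_c = if (model %in% c("M2", "M3")) raw$lambda_c else NA_real_,
    lambda_h = raw$lambda_h
  )
  structure(
    list(samples = samples, model = model, target = task$target_name,
         candidates = cov_names, hyper = hyper, config = config,
         fixed_changepoints = if (fix_tau) init_tau else NULL,
         seed = seed, accept = raw$accept),
    class = "nhdbn_chain"
  )
}

#' @export
print.nhdbn_chain <- function(x, ...) {
  cat(sprintf("<nhdbn_chain> %s chain for target %s: %d retained samples\n",
              x$model, x$target, nrow(x$samples)))
  cat(sprintf("  mean |parents| = %.2f, mean segments = %.2f\n",
              mean(x$samples$n_parents), mean(x$samples$n_segments)))
  invisible(x)
}

#' @rdname run_chain
#' @param x An `nhdbn_chain` object.
#' @param ... Unused.
#' @export
tidy.nhdbn_chain <- function(x, ...) {
  x$samples
}

#' @rdname run_chain
#' @export
glance.nhdbn_chain <- function(x, ...) {
  acc <- x$accept
  tibble::tibble(
    model = x$model,
    target = x$target,
    n_samples = nrow(x$samples),
    mean_log_marginal = mean(x$samples$log_marginal),
    mean_n_parents = mean(x$samples$n_parents),
    mean_n_segments = mean(x$samples$n_segments),
    parent_acceptance = if (acc$parent_attempted > 0) {
      acc$parent_accepted / acc$parent_attempted
    } else NA_real_,
    changepoint_acceptance = if (acc$changepoint_attempted > 0) {
      acc$changepoint_accepted / acc$changepoint_attempted
    } else NA_real_
  )
}

#' Posterior parent-inclusion probabilities of one chain
#'
#' Fraction of retained samples in which each candidate covariate is in
#' the parent set.
#'
#' @param chain An [run_chain()] result.
#' @return A tibble with columns `parent`, `child`, `score`.
#' @export
parent_scores <- function(chain) {
  stopifnot(inherits(chain, "nhdbn_chain"))
  W <- nrow(chain$samples)
  counts <- table(factor(unlist(chain$samples$parents),
                         levels = chain$candidates))
  tibble::tibble(
    parent = chain$candidates,
    child = chain$target,
    score = as.numeric(counts) / W
  )
}

#' Posterior coupling probabilities of one fixed-segmentation M3 chain
#'
#' For a partially coupled chain run with fixed changepoints, the
#' posterior probability that each segment `h = 2..H` is coupled to its
#' predecessor.
#'
#' @param chain An [run_chain()] result for model `"M3"` with fixed
#'   changepoints.
#' @return A tibble with columns `segment` (`2..H`) and `prob_coupled`.
#' @export
coupling_probabilities <- function(chain) {
  stopifnot(inherits(chain, "nhdbn_chain"), chain$model == "M3",
            !is.null(chain$fixed_changepoints))
  H <- length(chain$fixed_changepoints) + 1L
  mat <- do.call(rbind, chain$samples$delta)
  tibble::tibble(segment = seq_len(H)[-1L], prob_coupled = colMeans(mat))
}
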