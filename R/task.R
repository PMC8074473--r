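#' Build a lag-1 regression task for one target node
#'
#' Regulatory interactions are modelled with a lag of one time point: the
#' value of the target at time `t+1` is regressed on the values of all
#' other nodes at time `t`.  An `N`-by-`(T+1)` matrix therefore yields `T`
#' observations with `n = N - 1` candidate covariates.  Lag pairs that
#' straddle a declared experiment boundary are masked invalid, since the
#' last column of one experiment and the first column of the next are not
#' one sampling interval apart.
#'
#' @param data An [expression_data()] object.
#' @param target Target node: its index or name.
#' @return An object of class `nhdbn_task` with elements
#'   \describe{
#'     \item{response}{numeric vector of length `T`, the target at times
#'       `2..T+1`.}
#'     \item{covariates}{`T`-by-`n` matrix; row `t` holds the other nodes'
#'       values at time `t`, columns named by node.}
#'     \item{valid}{logical vector of length `T`; `FALSE` where the lag
#'       pair crosses an experiment boundary.}
#'     \item{target_index, target_name, n, T}{bookkeeping.}
#'   }
#' @examples
#' d <- expression_data(matrix(rnorm(30), 3, 10,
#'   dimnames = list(c("A", "B", "C"), NULL)), boundaries = 5)
#' task <- build_regression_task(d, "A")
#' sum(task$valid)  # 8: one of the 9 lag pairs crosses the boundary
#' @export
build_regression_task <- function(data, target) {
  stopifnot(inherits(data, "nhdbn_data"))
  if (is.character(target)) {
    idx <- match(target, data$node_names)
    if (is.na(idx)) stop("unknown target node: ", target, call. = FALSE)
    target <- idx
  }
  target <- as.integer(target)
  N <- nrow(data$values)
  if (target < 1L || target > N) {
    stop("target index out of range", call. = FALSE)
  }
  Tn <- ncol(data$values) - 1L
  response <- data$values[target, -1L]
  covariates <- t(data$values[-target, seq_len(Tn), drop = FALSE])
  colnames(covariates) <- data$node_names[-target]
  # canonical column order, so chains seeded by node name are invariant
  # to the row order of the input matrix
  covariates <- covariates[, order(colnames(covariates)), drop = FALSE]
  # observation t pairs column t with column t+1; invalid when column t+1
  # starts a new experiment
  valid <- rep(TRUE, Tn)
  valid[data$boundaries - 1L] <- FALSE
  if (!any(valid)) {
    stop("all observations are masked by experiment boundaries",
         call. = FALSE)
  }
  structure(
    list(response = unname(response), covariates = covariates,
         valid = valid, target_index = target,
         target_name = data$node_names[target],
         n = N - 1L, T = Tn),
    class = "nhdbn_task"
  )
}

#' @export
print.nhdbn_task <- function(x, ...) {
  cat(sprintf(
    "<nhdbn_task> target %s: T = %d observations (%d valid), n = %d candidate covariates\n",
    x$target_name, x$T, sum(x$valid), x$n))
  invisible(x)
}

#' Split a regression task into segment-wise response/design blocks
#'
#' Changepoints `tau` (integers in `1..T-1`) divide the `T` lagged
#' observations into `H = length(tau) + 1` segments.  Observation `t`
#' belongs to segment `h` when `tau[h-1] < t <= tau[h]`, with the
#' conventions `tau[0] = 0` and `tau[H] = T` so that every observation is
#' covered.  Each segment's design matrix has a leading intercept column
#' followed by the covariate columns selected by `parents`.  Observations
#' masked invalid in the task are dropped.
#'
#' @param task An [build_regression_task()] object.
#' @param tau Integer vector of changepoints, strictly increasing, each in
#'   `1..T-1`.  `integer()` means a single segment.
#' @param parents Covariate selection: integer indices into
#'   `task$covariates` columns, or column names.  May be empty
#'   (intercept-only model).
#' @param min_seg_len Minimum number of valid observations per segment
#'   (default 2); violated segmentations raise an error.
#' @return A list of `H` segments, each a list with `y` (response vector),
#'   `X` (design matrix with intercept column) and `t` (the 1-based
#'   observation indices included).
#' @examples
#' d <- expression_data(matrix(rnorm(4 * 8), 4, 8,
#'   dimnames = list(paste0("G", 1:4), NULL)))
#' task <- build_regression_task(d, 1)
#' segs <- segmentize(task, tau = c(2, 4), parents = "G2", min_seg_len = 2)
#' vapply(segs, function(s) length(s$y), integer(1))  # 2 2 3
#' @export
segmentize <- function(task, tau = integer(), parents = integer(),
                       min_seg_len = 2L) {
  stopifnot(inherits(task, "nhdbn_task"))
  tau <- as.integer(tau)
  if (length(tau)) {
    if (is.unsorted(tau, strictly = TRUE) ||
        any(tau < 1L) || any(tau >= task$T)) {
      stop("changepoints must be strictly increasing integers in 1..T-1",
           call. = FALSE)
    }
  }
  if (is.character(parents)) {
    idx <- match(parents, colnames(task$covariates))
    if (anyNA(idx)) {
      stop("unknown covariate(s): ",
           paste(parents[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    parents <- idx
  }
  parents <- as.integer(parents)
  bounds <- c(0L, tau, task$T)
  H <- length(tau) + 1L
  out <- vector("list", H)
  for (h in seq_len(H)) {
    t_idx <- seq.int(bounds[h] + 1L, bounds[h + 1L])
    t_idx <- t_idx[task$valid[t_idx]]
    if (length(t_idx) < min_seg_len) {
      stop(sprintf("segment %d has %d valid observation(s), below min_seg_len = %d",
                   h, length(t_idx), min_seg_len), call. = FALSE)
    }
    X <- cbind(1, task$covariates[t_idx, parents, drop = FALSE])
    colnames(X) <- c("(intercept)", colnames(task$covariates)[parents])
    out[[h]] <- list(y = task$response[t_idx], X = X, t = t_idx)
  }
  out
}

#' Place K fixed changepoints by repeated bisection of the longest segment
#'
#' Used when the data segmentation is imposed rather than inferred: the
#' first changepoint separates two known experimental phases, and each
#' further changepoint bisects the currently longest segment, until `K`
#' changepoints are set.  `K` changepoints yield `H = K + 1` segments.
#'
#' @param K Number of changepoints (`K >= 1`).
#' @param T Number of lagged observations.
#' @param first_boundary Location of the first changepoint (last
#'   observation of the first phase).
#' @param min_seg_len Minimum segment length that every resulting segment
#'   must respect.
#' @return Sorted integer vector of `K` changepoints.
#' @examples
#' fixed_changepoints(1, T = 35, first_boundary = 15)  # 15
#' fixed_changepoints(2, T = 35, first_boundary = 15)  # 15 25
#' @export
fixed_changepoints <- function(K, T, first_boundary, min_seg_len = 2L) {
  K <- as.integer(K)
  stopifnot(K >= 1L, first_boundary >= 1L, first_boundary < T)
  tau <- as.integer(first_boundary)
  while (length(tau) < K) {
    bounds <- c(0L, tau, as.integer(T))
    lens <- diff(bounds)
    h <- which.max(lens)  # earliest longest segment on ties
    new_cp <- bounds[h] + lens[h] %/% 2L
    if (new_cp %in% tau || new_cp == 0L) {
      stop("cannot place ", K, " changepoints on T = ", T,
           " observations", call. = FALSE)
    }
    tau <- sort(c(tau, new_cp))
  }
  lens <- diff(c(0L, tau, as.integer(T)))
  if (any(lens < min_seg_len)) {
    stop("placement infeasible under min_seg_len = ", min_seg_len,
         call. = FALSE)
  }
  tau
}
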