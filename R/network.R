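#' Construct a directed network object
#'
#' @param nodes Character vector of node identifiers.
#' @param edges A data frame (or tibble) with columns `parent` and
#'   `child`; every edge must reference known nodes and self-loops are
#'   disallowed.
#' @return An object of class `nhdbn_network`.
#' @export
nhdbn_network <- function(nodes, edges) {
  nodes <- as.character(nodes)
  edges <- tibble::as_tibble(edges)[, c("parent", "child")]
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  if (!all(edges$parent %in% nodes) || !all(edges$child %in% nodes)) {
    stop("edges reference unknown nodes", call. = FALSE)
  }
  if (any(edges$parent == edges$child)) {
    stop("self-loops are not allowed", call. = FALSE)
  }
  if (anyDuplicated(paste(edges$parent, edges$child))) {
    stop("duplicate edges", call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "nhdbn_network")
}

#' @export
print.nhdbn_network <- function(x, ...) {
  cat(sprintf("<nhdbn_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
tidy.nhdbn_network <- function(x, ...) x$edges

#' Infer a regulatory network from expression time series
#'
#' Runs one independent RJMCMC chain per target node (the lag-1
#' construction needs no acyclicity constraint, so parent sets decouple)
#' and merges the sampled parent sets into posterior edge scores.  Chains
#' are seeded deterministically from `(seed, node name)`, so re-running a
#' subset of nodes reproduces the full-run chains.
#'
#' @inheritParams run_chain
#' @param data An [expression_data()] object.
#' @param targets Optional subset of node names to run (default: all).
#' @param seed Master seed (integer).
#' @return An object of class `nhdbn_fit`: per-node chains, a `scores`
#'   tibble (`parent`, `child`, `score`) and metadata.
#' @export
infer_network <- function(data, model = "M3", hyper = nhdbn_hyper(),
                          config = chain_config(),
                          fixed_changepoints = NULL, seed = 1L,
                          targets = NULL) {
  stopifnot(inherits(data, "nhdbn_data"))
  model <- check_variant(model)
  if (is.null(targets)) targets <- data$node_names
  stopifnot(all(targets %in% data$node_names))
  chains <- lapply(targets, function(nm) {
    tryCatch(
      run_chain(build_regression_task(data, nm), model = model,
                hyper = hyper, config = config,
                fixed_changepoints = fixed_changepoints,
                seed = node_seed(seed, nm)),
      error = function(e) {
        stop("chain for target node '", nm, "' failed: ",
             conditionMessage(e), call. = FALSE)
      }
    )
  })
  names(chains) <- targets
  scores <- dplyr::bind_rows(lapply(chains, parent_scores))
  structure(
    list(chains = chains, scores = scores, nodes = data$node_names,
         targets = targets, model = model, hyper = hyper, config = config,
         fixed_changepoints = fixed_changepoints, seed = seed),
    class = "nhdbn_fit"
  )
}

#' @export
print.nhdbn_fit <- function(x, ...) {
  cat(sprintf("<nhdbn_fit> %s fit: %d target chains over %d nodes\n",
              x$model, length(x$chains), length(x$nodes)))
  top <- dplyr::slice_max(x$scores, .data$score, n = 3L, with_ties = FALSE)
  cat("  top edges:",
      paste(sprintf("%s->%s (%.2f)", top$parent, top$child, top$score),
            collapse = ", "), "\n")
  invisible(x)
}

#' @rdname infer_network
#' @param x An `nhdbn_fit` object.
#' @param ... Unused.
#' @export
tidy.nhdbn_fit <- function(x, ...) x$scores

#' @rdname infer_network
#' @export
glance.nhdbn_fit <- function(x, ...) {
  per_chain <- dplyr::bind_rows(lapply(x$chains, glance))
  tibble::tibble(
    model = x$model,
    n_nodes = length(x$nodes),
    n_chains = length(x$chains),
    n_samples = sum(per_chain$n_samples),
    mean_n_parents = mean(per_chain$mean_n_parents),
    mean_n_segments = mean(per_chain$mean_n_segments)
  )
}

#' Posterior edge scores
#'
#' The edge score of `parent -> child` is the fraction of retained
#' posterior samples of the child's chain whose parent set contains the
#' parent.
#'
#' @param x An [infer_network()] fit, or a list of [run_chain()] chains.
#' @return A tibble with columns `parent`, `child`, `score`.
#' @export
edge_scores <- function(x) {
  if (inherits(x, "nhdbn_fit")) return(x$scores)
  if (inherits(x, "nhdbn_chain")) return(parent_scores(x))
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1), "nhdbn_chain")))
  dplyr::bind_rows(lapply(x, parent_scores))
}

#' Edge scores as an N-by-N matrix
#'
#' @param scores An edge-score tibble or an `nhdbn_fit`.
#' @param nodes Node ordering for the matrix (defaults to the sorted
#'   union of names in the scores).
#' @return Matrix with `scores[i, j] = score of edge i -> j`; the
#'   diagonal is `NA`.
#' @export
score_matrix <- function(scores, nodes = NULL) {
  scores <- as_score_tibble(scores)
  if (is.null(nodes)) nodes <- sort(unique(c(scores$parent, scores$child)))
  m <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  m[cbind(match(scores$parent, nodes), match(scores$child, nodes))] <-
    scores$score
  diag(m) <- NA_real_
  m
}

as_score_tibble <- function(scores) {
  if (inherits(scores, "nhdbn_fit")) return(scores$scores)
  scores <- tibble::as_tibble(scores)
  stopifnot(all(c("parent", "child", "score") %in% names(scores)))
  scores
}

as_edge_set <- function(truth) {
  if (inherits(truth, "nhdbn_network")) truth <- truth$edges
  truth <- tibble::as_tibble(truth)
  stopifnot(all(c("parent", "child") %in% names(truth)))
  paste(truth$parent, truth$child, sep = "\r")
}

#' Precision-recall curve of edge scores against a known network
#'
#' Thresholds sweep over the distinct score values (plus a value below
#' the minimum, so the all-edges endpoint is included); at each threshold
#' the edges whose score strictly exceeds it are predicted.  Precision is
#' the fraction of predictions that are true edges; recall the fraction
#' of the `M` true edges recovered.
#'
#' @param scores Edge-score tibble (`parent`, `child`, `score`) or an
#'   `nhdbn_fit`.
#' @param truth True network: an [nhdbn_network()] or an edge data frame.
#' @return A tibble with columns `threshold`, `n_predicted`,
#'   `true_positives`, `recall`, `precision`, ordered by increasing
#'   recall.
#' @export
pr_curve <- function(scores, truth) {
  scores <- as_score_tibble(scores)
  truth_keys <- as_edge_set(truth)
  M <- length(truth_keys)
  stopifnot(M >= 1L)
  is_true <- paste(scores$parent, scores$child, sep = "\r") %in% truth_keys
  thresholds <- c(sort(unique(scores$score), decreasing = TRUE),
                  min(scores$score) - 1)
  rows <- lapply(thresholds, function(xi) {
    pred <- scores$score > xi
    n_pred <- sum(pred)
    if (n_pred == 0L) return(NULL)
    tp <- sum(pred & is_true)
    tibble::tibble(threshold = xi, n_predicted = n_pred,
                   true_positives = tp, recall = tp / M,
                   precision = tp / n_pred)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$recall, .data$n_predicted)
}

#' Area under the precision-recall curve
#'
#' Trapezoidal integration over the [pr_curve()] points after prepending
#' the left endpoint `(0, P_first)`, where `P_first` is the precision of
#' the smallest non-empty prediction set.  When all scores are identical
#' the curve is a single point and the area is that point's precision
#' times its recall.
#'
#' @inheritParams pr_curve
#' @param interpolation `"trapezoid"` (default) or `"step"`
#'   (right-continuous step function, a conservative alternative).
#' @return AUC value in `[0, 1]`.
#' @examples
#' truth <- data.frame(parent = "A", child = "B")
#' sc <- data.frame(parent = c("A", "B"), child = c("B", "A"),
#'                  score = c(0.9, 0.4))
#' precision_recall_auc(sc, truth)  # 1
#' @export
precision_recall_auc <- function(scores, truth,
                                 interpolation = c("trapezoid", "step")) {
  interpolation <- match.arg(interpolation)
  curve <- pr_curve(scores, truth)
  if (nrow(curve) == 1L) {
    return(curve$precision * curve$recall)
  }
  r <- c(0, curve$recall)
  p <- c(curve$precision[1L], curve$precision)
  dr <- diff(r)
  if (interpolation == "trapezoid") {
    sum(dr * (head(p, -1L) + p[-1L]) / 2)
  } else {
    sum(dr * p[-1L])
  }
}

#' Extract the k highest-scoring edges as a network prediction
#'
#' Ties at the cut are broken deterministically by lexicographic
#' `(parent, child)` order.
#'
#' @inheritParams pr_curve
#' @param k Number of edges to keep (`0 <= k <=` number of scored pairs).
#' @return An [nhdbn_network()] with the predicted edges.
#' @export
top_k_prediction <- function(scores, k) {
  scores <- as_score_tibble(scores)
  k <- as.integer(k)
  stopifnot(k >= 0L, k <= nrow(scores))
  nodes <- sort(unique(c(scores$parent, scores$child)))
  picked <- dplyr::slice_head(
    dplyr::arrange(scores, dplyr::desc(.data$score), .data$parent,
                   .data$child),
    n = k
  )
  nhdbn_network(nodes, picked[, c("parent", "child")])
}
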