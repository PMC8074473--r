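#' Bundled benchmark network topologies
#'
#' Two realistic topologies used throughout the synthetic studies:
#' `"raf"`, the RAF protein signalling pathway (11 nodes, 20 edges,
#' transcribed from the consensus diagram of Sachs and co-workers), and
#' `"yeast"`, the synthetically engineered IRMA 5-gene network in
#' *S. cerevisiae* (5 nodes, 8 edges, after Cantone and co-workers).
#' Both are shipped as plain edge-list files under `extdata/`.
#'
#' @param name `"raf"` or `"yeast"`.
#' @return An [nhdbn_network()].
#' @examples
#' fixture_network("yeast")
#' @export
fixture_network <- function(name = c("raf", "yeast")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("network_", name, ".tsv"),
                      package = "nhdbn", mustWork = TRUE)
  edges <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  nodes <- if (name == "raf") {
    c("RAF", "MEK", "ERK", "AKT", "JNK", "P38", "PKA", "PKC",
      "PIP2", "PIP3", "PLCG")
  } else {
    c("CBF1", "GAL4", "SWI5", "GAL80", "ASH1")
  }
  nhdbn_network(nodes, edges)
}

parents_of <- function(network, node) {
  network$edges$parent[network$edges$child == node]
}

# Draw standard-Gaussian coefficient vectors of length k+1 per node and
# normalize to a requested Euclidean norm.
draw_unit_coefs <- function(network, norm = 1) {
  setNames(lapply(network$nodes, function(nd) {
    k1 <- length(parents_of(network, nd)) + 1L
    w <- rnorm(k1)
    norm * w / sqrt(sum(w * w))
  }), network$nodes)
}

# Simulate an expression matrix on `network` given per-node per-segment
# coefficient matrices (list of (k+1) x H matrices), m observations per
# segment.  Values at time t+1 are intercept + lag-1 parent values times
# the segment coefficients, plus Gaussian observation noise.  With
# recursive = TRUE (the realistic default) the noisy observed values feed
# forward; otherwise a latent noise-free trajectory is propagated and
# noise is only added on output.
simulate_on_network <- function(network, coefs, m, H, noise_sd, recursive) {
  nodes <- network$nodes
  N <- length(nodes)
  Tn <- H * m
  latent <- matrix(0, N, Tn + 1L, dimnames = list(nodes, NULL))
  observed <- matrix(0, N, Tn + 1L, dimnames = list(nodes, NULL))
  latent[, 1L] <- rnorm(N)
  observed[, 1L] <- latent[, 1L]
  parent_idx <- lapply(nodes, function(nd) match(parents_of(network, nd),
                                                nodes))
  for (t in seq_len(Tn)) {
    h <- (t - 1L) %/% m + 1L
    src <- if (recursive) observed[, t] else latent[, t]
    for (i in seq_len(N)) {
      x <- c(1, src[parent_idx[[i]]])
      latent[i, t + 1L] <- sum(x * coefs[[i]][, h])
      observed[i, t + 1L] <- latent[i, t + 1L] + rnorm(1, sd = noise_sd)
    }
  }
  observed
}

new_simulation <- function(data, network, coefs, tau_true, extra) {
  structure(
    c(list(data = data, network = network, coefficients = coefs,
           tau_true = tau_true), extra),
    class = "nhdbn_simulation"
  )
}

#' @export
print.nhdbn_simulation <- function(x, ...) {
  cat(sprintf("<nhdbn_simulation> %s: %d nodes x %d time points, true changepoints {%s}\n",
              x$study, nrow(x$data$values), ncol(x$data$values),
              paste(x$tau_true, collapse = ", ")))
  invisible(x)
}

#' Synthetic RAF-pathway data with a chosen segment-coupling scenario
#'
#' Emulates the first benchmark study: data on the RAF pathway (11
#' nodes, 20 edges) with `H = 4` segments of `m = 10` observations each.
#' For every node the segment-1 coefficient vector is standard Gaussian,
#' normalized to Euclidean norm 1; for segments `h = 2, 3, 4` the
#' coefficients either stay identical (`delta_h = 1`, coupled) or flip
#' sign (`delta_h = 0`, uncoupled) according to the scenario.  Gaussian
#' observation noise with standard deviation 0.05 is added element-wise.
#' The eight scenarios are the vectors `(delta_2, delta_3, delta_4)` in
#' `{0,1}^3` (segment 1 is uncoupled by definition).
#'
#' @param scenario Coupling scenario: a binary vector of length 3, or a
#'   string such as `"011"` / `"0011"` (a leading `delta_1 = 0` digit is
#'   tolerated and dropped).
#' @param m Observations per segment (default 10).
#' @param noise_sd Observation noise standard deviation (default 0.05).
#' @param seed Optional integer seed.
#' @param recursive Should noisy observed values feed forward into the
#'   next time point (default `TRUE`), or should a latent noise-free
#'   trajectory be propagated?
#' @return An `nhdbn_simulation`: `data` (an [expression_data()] with
#'   `4 m + 1` columns), `network`, per-node `coefficients`
#'   (`(k+1)`-by-4 matrices), `tau_true`, `delta_true`, `scenario`.
#' @export
generate_study1 <- function(scenario = c(1, 1, 1), m = 10L,
                            noise_sd = 0.05, seed = NULL,
                            recursive = TRUE) {
  delta_true <- parse_scenario(scenario)
  stopifnot(m >= 2L)
  H <- 4L
  network <- fixture_network("raf")
  local_seed(seed, {
    w1 <- draw_unit_coefs(network, norm = 1)
    coefs <- lapply(w1, function(w) {
      out <- matrix(0, length(w), H)
      out[, 1L] <- w
      for (h in 2:H) {
        out[, h] <- if (delta_true[h - 1L] == 1L) out[, h - 1L] else -out[, h - 1L]
      }
      out
    })
    observed <- simulate_on_network(network, coefs, m, H, noise_sd,
                                    recursive)
    new_simulation(
      expression_data(observed), network, coefs,
      tau_true = m * seq_len(H - 1L),
      extra = list(study = "study1", delta_true = delta_true,
                   scenario = paste(c(0L, delta_true), collapse = ""),
                   m = m, noise_sd = noise_sd, seed = seed)
    )
  })
}

parse_scenario <- function(scenario) {
  if (is.character(scenario)) {
    scenario <- as.integer(strsplit(scenario, "")[[1L]])
  }
  scenario <- as.integer(scenario)
  if (length(scenario) == 4L) {
    if (scenario[1L] != 0L) {
      stop("delta_1 is fixed at 0; scenario must start with 0",
           call. = FALSE)
    }
    scenario <- scenario[-1L]
  }
  if (length(scenario) != 3L || !all(scenario %in% c(0L, 1L))) {
    stop("scenario must be 3 binary indicators (delta_2, delta_3, delta_4)",
         call. = FALSE)
  }
  scenario
}

#' Synthetic yeast-network data with moderate mid-series coupling
#'
#' Emulates the second benchmark study on the 5-gene yeast network
#' (8 edges), `H = 4` segments of `m` observations each.  Per node two
#' standard-Gaussian vectors are drawn and re-normalized: the first to
#' Euclidean norm 1, the second to norm 0.5.  Segments 1 and 2 share the
#' first vector; segments 3 and 4 share the re-normalized sum of the two
#' vectors (again norm 1), so the transition between segments 2 and 3 is
#' a moderate change rather than an identity or a sign flip.
#'
#' @param m Observations per segment; the study varies `m` in `2..12`
#'   (other values are allowed).
#' @inheritParams generate_study1
#' @return An `nhdbn_simulation` (see [generate_study1()]).
#' @export
generate_study2 <- function(m = 8L, noise_sd = 0.05, seed = NULL,
                            recursive = TRUE) {
  stopifnot(m >= 2L)
  H <- 4L
  network <- fixture_network("yeast")
  local_seed(seed, {
    w_diamond <- draw_unit_coefs(network, norm = 1)
    w_star <- draw_unit_coefs(network, norm = 0.5)
    coefs <- setNames(lapply(network$nodes, function(nd) {
      wd <- w_diamond[[nd]]
      ws <- w_star[[nd]]
      w34 <- (wd + ws) / sqrt(sum((wd + ws)^2))
      cbind(wd, wd, w34, w34, deparse.level = 0)
    }), network$nodes)
    observed <- simulate_on_network(network, coefs, m, H, noise_sd,
                                    recursive)
    new_simulation(
      expression_data(observed), network, coefs,
      tau_true = m * seq_len(H - 1L),
      extra = list(study = "study2", w_diamond = w_diamond,
                   w_star = w_star, m = m, noise_sd = noise_sd,
                   seed = seed)
    )
  })
}
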