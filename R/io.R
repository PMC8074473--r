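#' Write an edge-score table to TSV
#'
#' @param scores Edge-score tibble or `nhdbn_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_scores <- function(scores, path) {
  scores <- as_score_tibble(scores)
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge-score table from TSV
#'
#' @param path Path to a TSV with columns `parent`, `child`, `score`.
#' @return An edge-score tibble.
#' @export
read_edge_scores <- function(path) {
  out <- tibble::as_tibble(read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
  stopifnot(all(c("parent", "child", "score") %in% names(out)))
  out
}

#' Read a true network from a 2-column edge-list TSV
#'
#' @param path Path to a TSV with columns `parent` and `child` (header
#'   optional).
#' @param nodes Optional node set; defaults to the nodes named in the
#'   edges.
#' @return An [nhdbn_network()].
#' @export
read_network <- function(path, nodes = NULL) {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1L]]
  header <- identical(tolower(first[1:2]), c("parent", "child"))
  edges <- read.table(path, header = header, sep = "\t",
                      stringsAsFactors = FALSE)
  names(edges)[1:2] <- c("parent", "child")
  if (is.null(nodes)) nodes <- sort(unique(c(edges$parent, edges$child)))
  nhdbn_network(nodes, edges)
}

file_checksum <- function(path) unname(tools::md5sum(path))

#' Read a flat key=value run configuration
#'
#' Parses a plain-text configuration file with one `key = value` pair per
#' line (`#` comments allowed) into the model choice, hyperparameters and
#' chain configuration.  Recognized keys: `model` (M1..M4), `seed`, the
#' [nhdbn_hyper()] arguments (`alpha_sigma`, `beta_sigma`, `alpha_u`,
#' `beta_u`, `alpha_c`, `beta_c`, `a`, `b`, `p_cp`, `fan_in`) and the
#' [chain_config()] arguments (`iterations`, `burn_in_fraction`,
#' `thinning`, `min_seg_len`).  Unknown keys raise an error; omitted keys
#' keep their defaults.
#'
#' @param path Path to the configuration file.
#' @return A list with elements `model`, `seed`, `hyper` and `config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  if (any(lengths(kv) != 2L)) {
    stop("configuration lines must be 'key = value'", call. = FALSE)
  }
  vals <- setNames(vapply(kv, `[[`, character(1), 2L),
                   vapply(kv, `[[`, character(1), 1L))
  hyper_keys <- c("alpha_sigma", "beta_sigma", "alpha_u", "beta_u",
                  "alpha_c", "beta_c", "a", "b", "p_cp", "fan_in")
  config_keys <- c("iterations", "burn_in_fraction", "thinning",
                   "min_seg_len")
  unknown <- setdiff(names(vals), c("model", "seed", hyper_keys, config_keys))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  num <- function(keys) {
    out <- lapply(vals[intersect(keys, names(vals))], as.numeric)
    if (anyNA(out, recursive = TRUE)) {
      stop("non-numeric configuration value", call. = FALSE)
    }
    out
  }
  list(
    model = if ("model" %in% names(vals)) {
      match.arg(vals[["model"]], model_variants)
    } else "M3",
    seed = if ("seed" %in% names(vals)) as.integer(vals[["seed"]]),
    hyper = do.call(nhdbn_hyper, num(hyper_keys)),
    config = do.call(chain_config, num(config_keys))
  )
}

#' Write a full inference run to a directory
#'
#' Produces `edge_scores.tsv`, one `samples_<node>.tsv` per target chain
#' (draw index, parent-set size, parent names, changepoints, coupling
#' state, log marginal likelihood), and `manifest.json` recording the
#' configuration, master seed, per-node chain seeds and package version
#' -- enough to reproduce the run bit-identically.
#'
#' @param fit An [infer_network()] result.
#' @param outdir Output directory (created if absent; existing files are
#'   overwritten with a warning).
#' @param input_path Optional path of the input expression file, recorded
#'   with its checksum in the manifest.
#' @return Invisibly, the manifest list.
#' @export
write_results <- function(fit, outdir, input_path = NULL) {
  stopifnot(inherits(fit, "nhdbn_fit"))
  if (!dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  } else if (length(list.files(outdir))) {
    warning("overwriting existing files in ", outdir, call. = FALSE)
  }
  write_edge_scores(fit$scores, file.path(outdir, "edge_scores.tsv"))
  for (nm in names(fit$chains)) {
    ch <- fit$chains[[nm]]
    flat <- data.frame(
      draw = ch$samples$draw,
      n_parents = ch$samples$n_parents,
      parents = vapply(ch$samples$parents, paste, character(1),
                       collapse = ","),
      tau = vapply(ch$samples$tau, paste, character(1), collapse = ","),
      delta = vapply(ch$samples$delta, paste, character(1), collapse = ","),
      lambda_u = ch$samples$lambda_u,
      lambda_c = ch$samples$lambda_c,
      lambda_h = vapply(ch$samples$lambda_h, paste, character(1),
                        collapse = ","),
      log_marginal = ch$samples$log_marginal
    )
    write.table(flat, file.path(outdir, paste0("samples_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    package = "nhdbn",
    version = as.character(utils::packageVersion("nhdbn")),
    model = fit$model,
    seed = fit$seed,
    node_seeds = setNames(
      lapply(names(fit$chains), function(nm) node_seed(fit$seed, nm)),
      names(fit$chains)
    ),
    hyper = unclass(fit$hyper),
    config = unclass(fit$config),
    fixed_changepoints = fit$fixed_changepoints,
    targets = fit$targets,
    input = if (!is.null(input_path)) {
      list(path = input_path, md5 = file_checksum(input_path))
    },
    acceptance = lapply(fit$chains, `[[`, "accept")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
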