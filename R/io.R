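#' Write a table as TSV
#'
#' Tab-separated, UTF-8, header row, numbers formatted to 12 significant
#' digits; the format read back by \code{\link{read_tsv_table}}.
#'
#' @param df a data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  fmt <- df
  num <- vapply(fmt, is.numeric, logical(1)) &
    !vapply(fmt, is.integer, logical(1))
  fmt[num] <- lapply(fmt[num], function(v) formatC(v, digits = 12, format = "g"))
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV written by this package
#'
#' @param path input path.
#' @return a data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = NA, check.names = FALSE)
}

#' Run metadata
#'
#' Every run writes a JSON metadata object echoing the configuration, the
#' seed, the package version, wall time and outcome counts.
#'
#' @param config a flat named list of configuration values.
#' @param seed the RNG seed of the run.
#' @param wall_time_s elapsed seconds.
#' @param outcome_counts optional named list/vector of outcome tallies.
#' @return a list of class \code{run_metadata}.
#' @export
run_metadata <- function(config, seed, wall_time_s = NA_real_,
                         outcome_counts = NULL) {
  structure(list(
    package = "gcsweep",
    version = as.character(utils::packageVersion("gcsweep")),
    seed = seed,
    config = config,
    wall_time_s = wall_time_s,
    outcome_counts = outcome_counts),
    class = "run_metadata")
}

#' Write a JSON summary or metadata object
#'
#' @param x a list (e.g. \code{\link{run_metadata}} or a result summary).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_json_summary <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Parse a flat key-value configuration file, with flag overrides
#'
#' Configurations are flat YAML mappings (key: value, one per line). Values
#' given in \code{overrides} replace file values. Contradictory settings -
#' affinity-bias parameters together with \code{model: trait_bias} or
#' vice versa - are rejected with an error naming the offending key.
#'
#' @param path path to a YAML config file, or NULL for overrides only.
#' @param overrides named list of values taking precedence over the file.
#' @return a named list of configuration values.
#' @export
parse_config <- function(path = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- yaml::read_yaml(path)
    if (!is.list(cfg)) stop("config must be a flat key-value mapping")
  }
  cfg[names(overrides)] <- overrides
  if (!is.null(cfg$model)) {
    if (cfg$model == "trait_bias" &&
        (!is.null(cfg$beta1) || !is.null(cfg$beta2)))
      stop("beta1/beta2 given but model is trait_bias")
    if (cfg$model == "affinity" &&
        (!is.null(cfg$gamma1) || !is.null(cfg$gamma2)))
      stop("gamma1/gamma2 given but model is affinity")
  }
  cfg
}

#' Write a flat configuration file
#'
#' @param cfg named list as returned by \code{\link{parse_config}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Build a transmission model from a flat configuration
#'
#' @param cfg named list with \code{model} and the matching bias parameters;
#'   defaults follow the package-wide illustration values
#'   (affinity beta2 = 0.001, trait-bias gamma2 = 0.5).
#' @return a \code{\link{transmission_model}}.
#' @export
model_from_config <- function(cfg) {
  variant <- cfg$model %||% "affinity"
  if (variant == "affinity")
    affinity_bias(cfg$beta1 %||% 0.05, cfg$beta2 %||% 0.001)
  else
    trait_bias(cfg$gamma1 %||% 0.75, cfg$gamma2 %||% 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate deterministic test fixtures
#'
#' Small synthetic inputs for testing the statistics and IO layers:
#' haplotype tables with a hard-sweep spectrum (one dominant haplotype), a
#' soft-sweep spectrum (two co-dominant haplotypes), a neutral
#' (high-entropy) spectrum, and a canned deterministic sweep trajectory.
#' Files are byte-identical for a given seed.
#'
#' @param kind one of \code{"haplotypes_hard"}, \code{"haplotypes_soft"},
#'   \code{"haplotypes_neutral"}, \code{"trajectory"}.
#' @param seed RNG seed.
#' @param dir output directory (created if needed).
#' @return the path of the file written.
#' @export
generate_fixtures <- function(kind = c("haplotypes_hard", "haplotypes_soft",
                                       "haplotypes_neutral", "trajectory"),
                              seed = 1L, dir = tempdir()) {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(seed)
  path <- file.path(dir, paste0(kind, ".tsv"))
  labels <- vapply(0:31, function(h)
    paste(rev(as.integer(intToBits(h))[1:5]), collapse = ""), character(1))
  if (kind == "trajectory") {
    traj <- run_sweep(pheno_state(1e-6, 1, 0.5), fitness_params(0, 0.1),
                      affinity_bias(0.05, 0.001))
    write_tsv_table(data.frame(generation = traj$t, x = traj$x, Q = traj$Q,
                               R = traj$R, p = traj$p, H_rel = traj$H_rel),
                    path)
    return(path)
  }
  n_hap <- 8L
  hl <- sample(labels, n_hap)
  freqs <- switch(kind,
    haplotypes_hard = c(0.99, rep(0.01 / (n_hap - 1), n_hap - 1)),
    haplotypes_soft = c(0.45, 0.45, rep(0.1 / (n_hap - 2), n_hap - 2)),
    haplotypes_neutral = {
      w <- stats::rexp(n_hap) + 0.5
      w / sum(w)
    })
  counts <- round(freqs * 10000)
  write_tsv_table(data.frame(group = kind, sweep_id = 1L, haplotype = hl,
                             count = as.integer(counts)), path)
  path
}
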