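#' Read and validate a pipeline run configuration
#'
#' A run config is a YAML file (or equivalent list) with a `seed`, an
#' `output_dir`, exactly one input source — `simulate` (two texture arms
#' with per-arm scene overrides) or `inputs` (a list of image records
#' with `path`, `sample_id`, `group`) — and optional parameter blocks
#' `glcm`, `segmentation`, and `pattern_threshold`. Validation errors
#' name the offending keys.
#'
#' @param config path to a YAML file, or a list with the same structure.
#' @return The validated config list (class `run_config`).
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML file or a list")
  bad <- character()
  if (is.null(config$seed)) bad <- c(bad, "seed (required)")
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp) {
    bad <- c(bad, "exactly one of `simulate` or `inputs` must be given")
  }
  if (has_inp) {
    for (i in seq_along(config$inputs)) {
      rec <- config$inputs[[i]]
      if (is.null(rec$path)) {
        bad <- c(bad, sprintf("inputs[%d].path (required)", i))
      } else if (!file.exists(rec$path)) {
        bad <- c(bad, sprintf("inputs[%d].path: file not found '%s'", i, rec$path))
      }
      if (is.null(rec$group)) bad <- c(bad, sprintf("inputs[%d].group (required)", i))
    }
  }
  if (has_sim) {
    if (is.null(config$simulate$n_samples)) {
      bad <- c(bad, "simulate.n_samples (required)")
    }
  }
  if (length(bad)) {
    stop(sprintf("invalid run config:\n  - %s", paste(bad, collapse = "\n  - ")))
  }
  class(config) <- c("run_config", "list")
  config
}

#' Run the end-to-end texture pipeline
#'
#' Orchestrates simulate (or load) -> segment -> per-nucleus texture ->
#' per-sample means -> percent change, chromatin-pattern call and
#' per-feature group comparisons, writing all artifacts under the output
#' directory with a `manifest.json` recording the resolved configuration
#' and per-stage record counts. Outputs carry no timestamps, so reruns
#' with the same config and seed are byte-identical.
#'
#' @param config path to a YAML run config, or a config list (see
#'   [read_run_config()]).
#' @param output_dir overrides the config's `output_dir`.
#' @param quiet suppress progress messages.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config, output_dir = NULL, quiet = FALSE) {
  cfg <- read_run_config(config)
  outdir <- output_dir %||% cfg$output_dir %||% stop("no output_dir given")
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  gp <- do.call(glcm_params, as_param_list(cfg$glcm))
  sp <- do.call(segmentation_params, as_param_list(cfg$segmentation))
  threshold <- cfg$pattern_threshold %||% 5

  # -- acquire samples: (sample_id, group, dapi image, optional truth) ------
  samples <- if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    say("simulate", "%d samples per arm", sim$n_samples)
    arms <- list(control = sim$control %||% list(),
                 treated = sim$treated %||% list())
    idx <- 0L
    out <- list()
    for (arm in names(arms)) {
      for (i in seq_len(sim$n_samples)) {
        idx <- idx + 1L
        args <- utils::modifyList(as_param_list(sim$scene), as_param_list(arms[[arm]]))
        args$texture_regime <- arm
        args$seed <- as.integer(cfg$seed) + idx
        scene <- generate_texture_scene(do.call(scene_spec, args))
        out[[idx]] <- list(sample_id = sprintf("%s_%02d", arm, i), group = arm,
                           dapi = scene$channels$dapi)
      }
    }
    out
  } else {
    lapply(seq_along(cfg$inputs), function(i) {
      rec <- cfg$inputs[[i]]
      list(sample_id = rec$sample_id %||% sprintf("sample_%02d", i),
           group = rec$group,
           dapi = read_image(rec$path, rec$channel %||% 1L))
    })
  }

  dir.create(file.path(outdir, "texture"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "summary"), recursive = TRUE, showWarnings = FALSE)

  # -- segment + texture per sample ----------------------------------------
  per_nucleus <- list()
  sample_rows <- list()
  for (s in samples) {
    nuclei <- segment_nuclei(s$dapi, sp)
    prof <- nucleus_texture_profile(s$dapi, nuclei, gp)
    say("texture", "%s: %d nuclei", s$sample_id, prof$n_nuclei)
    if (prof$n_nuclei > 0) {
      per_nucleus[[s$sample_id]] <- cbind(
        data.frame(sample_id = s$sample_id, group = s$group),
        prof$per_nucleus)
    }
    sample_rows[[s$sample_id]] <- cbind(
      data.frame(sample_id = s$sample_id, group = s$group,
                 n_nuclei = prof$n_nuclei),
      as.data.frame(as.list(prof$sample_means)))
  }
  per_nucleus <- do.call(rbind, c(per_nucleus, list(make.row.names = FALSE)))
  per_nucleus <- per_nucleus[, texture_table_columns()]
  sample_means <- do.call(rbind, c(sample_rows, list(make.row.names = FALSE)))
  write_table(per_nucleus, file.path(outdir, "texture", "per_nucleus.csv"))
  write_table(sample_means, file.path(outdir, "texture", "sample_means.csv"))

  # -- group summaries ------------------------------------------------------
  feats <- c("asm", "contrast", "correlation", "idm", "entropy")
  grp_means <- function(g) {
    rows <- sample_means[sample_means$group == g, feats, drop = FALSE]
    vapply(rows, mean, numeric(1), na.rm = TRUE)
  }
  artifacts <- c("texture/per_nucleus.csv", "texture/sample_means.csv")
  counts <- list(samples = nrow(sample_means), nuclei = nrow(per_nucleus))
  if (all(c("control", "treated") %in% sample_means$group)) {
    pct <- percent_change(grp_means("treated"), grp_means("control"))
    pattern <- interpret_chromatin_pattern(pct, threshold = threshold)
    cmp <- compare_texture_groups(
      sample_means[sample_means$group == "control", , drop = FALSE],
      sample_means[sample_means$group == "treated", , drop = FALSE])
    jsonlite::write_json(
      list(feature_means = list(control = as.list(grp_means("control")),
                                treated = as.list(grp_means("treated"))),
           percent_change = as.list(pct)),
      file.path(outdir, "summary", "percent_change.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(
      list(homogeneity = pattern$homogeneity,
           heterogeneity = pattern$heterogeneity,
           contrast = pattern$contrast_pattern,
           threshold_pct = threshold, votes = pattern$votes),
      file.path(outdir, "summary", "pattern_call.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_table(cmp, file.path(outdir, "summary", "comparisons.csv"))
    artifacts <- c(artifacts, "summary/percent_change.json",
                   "summary/pattern_call.json", "summary/comparisons.csv")
    counts$comparisons <- nrow(cmp)
    say("compare", "pattern: homogeneity %s, heterogeneity %s, contrast %s",
        pattern$homogeneity, pattern$heterogeneity, pattern$contrast_pattern)
  }

  # the config echo omits output_dir so that runs into different
  # directories remain byte-identical
  cfg_echo <- unclass(cfg)
  cfg_echo$output_dir <- NULL
  manifest <- list(package = "chromtex",
                   version = as.character(utils::packageVersion("chromtex")),
                   seed = cfg$seed,
                   config = cfg_echo,
                   glcm_params = unclass(gp),
                   segmentation_params = unclass(sp),
                   record_counts = counts,
                   artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_param_list <- function(x) {
  if (is.null(x)) return(list())
  x <- as.list(x)
  # YAML gives plain lists; coerce length-2 numeric vectors written as
  # lists (e.g. nucleus_radius_range) back to vectors
  lapply(x, function(v) if (is.list(v)) unlist(v) else v)
}
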