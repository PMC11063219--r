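#' Default run configuration
#'
#' Bundles every component's parameters with a master seed. The configuration
#' can be written to / read from YAML or JSON, so runs are fully described by
#' one file.
#'
#' @param n_subjects Cohort size.
#' @param agent An `agent_config`.
#' @param max_len Encoded path length for the phase classifier.
#' @param epochs,lr Classifier training epochs and Adam learning rate.
#' @param shape Volume dimensions for the synthetic PE maps.
#' @param regions List of region corner/side specs
#'   (`list(corner = c(x, y, z), side = s)`).
#' @param bandwidth,sigma_explore,sigma_exploit,sigma_background Pattern
#'   model parameters, see [pattern_model()].
#' @param cube_side,stride RSA searchlight settings.
#' @param n_perm Permutations for FWE inference.
#' @param seed Master seed; every stage derives its stream from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(n_subjects = 25L, agent = agent_config(),
                       max_len = 20L, epochs = 100L, lr = 0.001,
                       shape = c(20L, 20L, 20L),
                       regions = list(list(corner = c(3L, 3L, 3L), side = 7L),
                                      list(corner = c(12L, 12L, 12L), side = 7L)),
                       bandwidth = 2, sigma_explore = 0.8,
                       sigma_exploit = 0.2, sigma_background = 1,
                       cube_side = 3L, stride = 1L, n_perm = 10000L,
                       seed = 1L) {
  if (n_subjects < 1L) stop("config invalid: n_subjects must be >= 1")
  stopifnot(inherits(agent, "agent_config"))
  structure(as.list(environment()), class = "run_config")
}

#' Read / write a run configuration file
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON (`.json`) file.
#' @return `read_run_config`: a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  agent <- do.call(agent_config, raw$agent)
  raw$agent <- NULL
  if (!is.null(raw$regions) && is.data.frame(raw$regions))
    raw$regions <- lapply(seq_len(nrow(raw$regions)), function(i)
      list(corner = unlist(raw$regions$corner[i]), side = raw$regions$side[i]))
  do.call(run_config, c(raw, list(agent = agent)))
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  out <- unclass(config)
  out$agent <- unclass(out$agent)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(out, path)
  else jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(lapply(unclass(config), unclass), tmp,
                       auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

msg <- function(quiet, ...) if (!quiet) message(sprintf(...))

#' Run the full pipeline: simulate, stage, test, and map
#'
#' Executes, in order: behavioral simulation of the cohort, phase-classifier
#' staging, the behavioral statistics battery, synthetic PE map generation,
#' per-subject searchlight RSA, and group TFCE permutation inference on the
#' exploitation-minus-exploration contrast. All stage outputs are returned;
#' when `outdir` is given, tables are written as CSV/JSON, maps as NIfTI, and
#' a manifest (config hash, seed, file checksums) records provenance.
#'
#' @param config A `run_config`.
#' @param outdir Optional output directory.
#' @param quiet Suppress progress messages.
#' @return List of class `pipeline_result`: `sessions`, `staged`, `stats`,
#'   `rho_maps` (per subject), `group` (a `group_result`), `peaks`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t_start <- Sys.time()
  set.seed(as.integer(config$seed))
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 4L)

  msg(quiet, "[simulate-behavior] %d subjects, seed %d",
      config$n_subjects, stage_seeds[1L])
  sessions <- simulate_cohort(config$n_subjects, config$agent, stage_seeds[1L])

  msg(quiet, "[stage] training phase classifiers")
  spec <- classifier_spec(2L * config$max_len, lr = config$lr,
                          epochs = config$epochs)
  staged <- stage_cohort(sessions, seed = stage_seeds[2L], spec = spec,
                         max_len = config$max_len)

  msg(quiet, "[stats] mixed models and auxiliary tests")
  stats_out <- stage_statistics(staged)

  msg(quiet, "[simulate-neural] %s volume",
      paste(config$shape, collapse = "x"))
  geom <- volume_geometry(config$shape)
  regions <- lapply(config$regions, function(r)
    cube_region(geom, r$corner, r$side))
  model <- pattern_model(regions, bandwidth = config$bandwidth,
                         sigma_explore = config$sigma_explore,
                         sigma_exploit = config$sigma_exploit,
                         sigma_background = config$sigma_background)
  set.seed(stage_seeds[3L])
  pe_seeds <- sample.int(.Machine$integer.max - 1L, length(staged))

  msg(quiet, "[rsa] searchlight per subject and stage")
  z_exploit <- list()
  z_explore <- list()
  for (i in seq_along(staged)) {
    pe <- generate_pe_maps(staged[[i]], geom, model, pe_seeds[i])
    sl <- searchlight_rsa(pe, config$cube_side, config$stride)
    z_exploit[[i]] <- sl$z$exploitation
    z_explore[[i]] <- sl$z$exploration
  }

  msg(quiet, "[rsa] group contrast, %d permutations", config$n_perm)
  contrast <- stage_contrast(z_exploit, z_explore)
  group <- permutation_fwe(contrast$diff, shape = config$shape,
                           n_perm = config$n_perm, seed = stage_seeds[4L])
  peaks <- peak_table(group)

  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   stage_seeds = stage_seeds,
                   n_subjects = config$n_subjects,
                   wall_seconds = as.numeric(difftime(Sys.time(), t_start,
                                                      units = "secs")),
                   r_version = as.character(getRversion()))
  result <- structure(
    list(sessions = sessions, staged = staged, stats = stats_out,
         z_maps = list(exploitation = z_exploit, exploration = z_explore),
         group = group, peaks = peaks, manifest = manifest),
    class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_outputs(result, config, outdir)
  result
}

write_pipeline_outputs <- function(result, config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_behavior_csv(result$sessions, file.path(outdir, "behavior_steps.csv"))
  utils::write.csv(staged_path_table(result$staged),
                   file.path(outdir, "staged_paths.csv"), row.names = FALSE)
  utils::write.csv(result$stats$lmm, file.path(outdir, "lmm_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$stats[c("accuracy_vs_chance",
                                      "path_count_paired",
                                      "accuracy_by_dim_anova")],
                       file.path(outdir, "auxiliary_tests.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in c("t_map", "tfce_map", "p_map")) {
    img <- result$group[[nm]]
    img[is.na(img)] <- 0
    RNifti::writeNifti(RNifti::asNifti(img),
                       file.path(outdir, paste0(sub("_map", "", nm), ".nii.gz")))
  }
  utils::write.csv(result$peaks, file.path(outdir, "peak_table.csv"),
                   row.names = FALSE)
  files <- list.files(outdir, full.names = TRUE)
  manifest <- c(result$manifest,
                list(files = lapply(files, function(f)
                  list(name = basename(f), md5 = unname(tools::md5sum(f))))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
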