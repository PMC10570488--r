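PIPELINE_SCHEMA <- list(
  cohort = c("n", "grid_shape", "voxel_size", "coupling", "marginals",
             "lesions", "flair", "dir"),
  segmentation = c("k", "min_component_size", "fit_method"),
  tracts = c("prob_threshold", "log_base", "zero_policy", "epsilon"),
  suvr = c("floor"),
  stats = c("alpha", "covariates"),
  top = c("cohort", "segmentation", "tracts", "suvr", "stats", "seed", "out_dir")
)

#' Read and validate a pipeline configuration
#'
#' @param config Path to a YAML file, or an already-parsed named list.
#' @return Validated configuration list with defaults filled in.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path", call. = FALSE)
  # YAML 1.1 parses a bare `n:` key as the boolean FALSE; map it back
  if (!is.null(config$cohort))
    names(config$cohort)[names(config$cohort) %in% c("FALSE", "no")] <- "n"
  unknown <- setdiff(names(config), PIPELINE_SCHEMA$top)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  for (blk in c("cohort", "segmentation", "tracts", "suvr", "stats")) {
    bad <- setdiff(names(config[[blk]]), PIPELINE_SCHEMA[[blk]])
    if (length(bad))
      stop(sprintf("unknown key(s) in config block '%s': %s", blk,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  defaults <- list(
    cohort = list(n = 40L, grid_shape = c(64L, 64L, 64L),
                  voxel_size = c(1, 1, 1.2), coupling = list(),
                  marginals = list(), lesions = list(),
                  flair = list(nawm_mu = 100, nawm_sigma = 10,
                               lesion_sd_frac = 0.5, noise = TRUE)),
    segmentation = list(k = 3, min_component_size = 3L,
                        fit_method = "histogram_ls"),
    tracts = list(prob_threshold = 0, log_base = 10,
                  zero_policy = "exclude", epsilon = 1e-3),
    suvr = list(floor = 1.17),
    stats = list(alpha = 0.05,
                 covariates = c("age", "sex", "apoe_e4_count", "icv")),
    seed = 1L, out_dir = NULL)
  merged <- utils::modifyList(defaults, config)
  if (!is.numeric(merged$seed) || length(merged$seed) != 1L)
    stop("config `seed` must be a single integer", call. = FALSE)
  merged
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full tract-WMH / SUVr pipeline
#'
#' Orchestrates generate -> segment -> tract volumes -> SUVr -> associate from
#' one configuration: simulates (or loads) a phantom cohort, segments WMH per
#' subject at the mean + k*SD threshold, intersects the WMH mask with each
#' tract, computes region SUVr against the cerebellum reference with the
#' amyloid-positivity floor, fits the four adjusted association models and
#' writes all stage tables plus a reproducibility manifest. Rerunning with
#' the same configuration reproduces every output byte-identically.
#'
#' @param config YAML path or configuration list (see
#'   [read_pipeline_config()]).
#' @param out_dir Output directory (overrides the config's `out_dir`; if both
#'   are NULL the tables are returned but not written).
#' @return List with `wmh` (per-subject segmentation summary), `tracts`
#'   (per-subject, per-tract burden), `suvr`, `results` (association table)
#'   and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_pipeline_config(config)
  if (is.null(out_dir)) out_dir <- cfg$out_dir

  cohort <- run_stage("generate", {
    if (!is.null(cfg$cohort$dir)) {
      read_cohort(cfg$cohort$dir)
    } else {
      simulate_cohort(
        n = cfg$cohort$n, seed = cfg$seed,
        space = build_phantom_space(cfg$cohort$grid_shape, cfg$cohort$voxel_size),
        coupling = do.call(coupling_config, cfg$cohort$coupling),
        marginals = do.call(cohort_marginals, cfg$cohort$marginals),
        lesions = do.call(lesion_model, cfg$cohort$lesions),
        flair = cfg$cohort$flair)
    }
  })
  space <- cohort$space
  vox <- space$voxel_size
  ids <- cohort$covariates$subject_id

  seg <- run_stage("segment", {
    rows <- lapply(ids, function(id) {
      fl <- cohort$subjects[[id]]$flair
      fit <- fit_wm_gaussian(fl, space$wm_mask,
                             method = cfg$segmentation$fit_method)
      thr <- wmh_threshold(fit, k = cfg$segmentation$k)
      wmh <- segment_wmh(fl, space$wm_mask, thr,
                         min_component_size = cfg$segmentation$min_component_size)
      list(mask = wmh,
           row = data.frame(subject_id = id, mu = fit$mu, sigma = fit$sigma,
                            threshold = thr,
                            wmh_volume_ml = wmh$total_volume_ml,
                            n_components_removed = wmh$n_components_removed,
                            stringsAsFactors = FALSE))
    })
    list(masks = stats::setNames(lapply(rows, `[[`, "mask"), ids),
         table = do.call(rbind, lapply(rows, `[[`, "row")))
  })

  tract_tab <- run_stage("tract-volumes", {
    rows <- do.call(rbind, lapply(ids, function(id) {
      vols <- vapply(TRACT_NAMES, function(tr)
        tract_wmh_volume(seg$masks[[id]],
                         binarize_tract(space$tract_masks[[tr]] + 0,
                                        cfg$tracts$prob_threshold),
                         vox), numeric(1))
      data.frame(subject_id = id, tract_name = TRACT_NAMES,
                 wmh_volume_ml = as.numeric(vols), stringsAsFactors = FALSE)
    }))
    log_transform_volumes(rows, base = cfg$tracts$log_base,
                          zero_policy = cfg$tracts$zero_policy,
                          epsilon = cfg$tracts$epsilon)
  })

  suvr_tab <- run_stage("suvr", {
    rows <- do.call(rbind, lapply(ids, function(id)
      subject_suvr_table(cohort$subjects[[id]]$pet, space$parcellation,
                         space$labels, space$cerebellum_mask, id)))
    apply_suvr_floor(rows, floor = cfg$suvr$floor)
  })

  results <- run_stage("associate", {
    run_family(suvr_tab, tract_tab, cohort$covariates,
               covariate_names = cfg$stats$covariates,
               alpha = cfg$stats$alpha)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("tractwmh")),
    seed = cfg$seed,
    config_hash = rlang::hash(cfg),
    n_subjects = length(ids),
    rows = list(wmh = nrow(seg$table), tracts = nrow(tract_tab),
                suvr = nrow(suvr_tab), results = nrow(results)),
    bonferroni_threshold = attr(results, "bonferroni_threshold"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(seg$table, file.path(out_dir, "wmh_volumes.csv"),
                     row.names = FALSE)
    utils::write.csv(tract_tab, file.path(out_dir, "tract_volumes.csv"),
                     row.names = FALSE)
    utils::write.csv(suvr_tab, file.path(out_dir, "suvr.csv"),
                     row.names = FALSE)
    utils::write.csv(format_results(results), file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    jsonlite::write_json(results, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(wmh = seg$table, tracts = tract_tab, suvr = suvr_tab,
       results = results, manifest = manifest)
}

# display rounding for the CSV mirror of the association table; the JSON
# sidecar keeps full precision
format_results <- function(results) {
  out <- results
  for (cn in c("std_beta", "p_value", "ci_low", "ci_high"))
    out[[cn]] <- round(out[[cn]], 3)
  for (cn in c("adj_r2", "cohens_f"))
    out[[cn]] <- round(out[[cn]], 2)
  out
}

#' Read a phantom cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.json` and the cohort files.
#' @return A `phantom_cohort`-shaped list usable by [run_pipeline()].
#' @export
read_cohort <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path))
    stop(sprintf("cohort manifest not found: %s", mf_path), call. = FALSE)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  rd <- function(name) read_volume(file.path(dir, name))
  labels <- unlist(jsonlite::read_json(file.path(dir, "labels.json"),
                                       simplifyVector = TRUE))
  tract_masks <- stats::setNames(lapply(TRACT_NAMES, function(tr)
    as_mask_array(rd(sprintf("tract_%s.nii.gz", tr)))), TRACT_NAMES)
  parc_vol <- rd("parcellation.nii.gz")
  parc <- array(as.integer(round(parc_vol$data)), dim = dim(parc_vol$data))
  composition <- dmn_composition()
  gm_region_masks <- composite_dmn_rois(parc, labels, composition)
  space <- structure(list(
    grid_shape = as.integer(mf$grid_shape),
    voxel_size = as.numeric(mf$voxel_size),
    wm_mask = as_mask_array(rd("wm_mask.nii.gz")),
    gm_region_masks = gm_region_masks,
    tract_masks = tract_masks,
    cerebellum_mask = as_mask_array(rd("cerebellum_mask.nii.gz")),
    parcellation = parc, labels = labels), class = "phantom_space")
  covariates <- utils::read.csv(file.path(dir, "covariates.csv"),
                                stringsAsFactors = FALSE)
  truth <- utils::read.csv(file.path(dir, "truth.csv"),
                           stringsAsFactors = FALSE)
  subjects <- stats::setNames(lapply(seq_len(nrow(mf$subjects)), function(i)
    list(flair = rd(mf$subjects$flair[i]), pet = rd(mf$subjects$pet[i]))),
    mf$subjects$subject_id)
  structure(list(space = space, covariates = covariates, truth = truth,
                 subjects = subjects),
            class = "phantom_cohort")
}
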