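#' Default pipeline configuration
#'
#' One place for every tunable the end-to-end run uses. The configuration is
#' a plain named list, fully serializable to YAML, and a run manifest
#' (config + seed + package version) is written alongside every output set.
#'
#' @param seed Master seed; every stochastic stage derives its own stream
#'   from it.
#' @return A named list of class `canopyn_config`.
#' @export
default_config <- function(seed = 1) {
  structure(
    list(
      seed = seed,
      design = list(
        sites = c("Lishi", "Ciyun"), stages = c("VGS", "FES"),
        n_rates = c(0, 150, 300, 450), replicates = 3, trees_per_cell = 4
      ),
      altitudes = c(60, 80, 100),
      allowed_altitudes = c(60, 80, 100),
      effect_profile = "table1_calibrated",
      sg = list(window = 11, polyorder = 2),
      screen = list(stat = "r2", stride = 1),
      structural = list(
        cell_size = 1, dist_threshold = 0.3, angle_threshold = 10,
        method = "full" # "full" = TIN chain; "direct" = clouds already normalized
      ),
      cloud = list(point_density = 250, ground_density = 25),
      models = list(
        families = c("MLR", "PLSR", "SVR", "RFR"),
        repeats = 5
      ),
      fusion = list(hsi_altitude = 100, lidar_altitude = 60)
    ),
    class = "canopyn_config"
  )
}

#' Read / write a pipeline configuration
#'
#' @param path YAML file path.
#' @return `read_config()` returns a validated `canopyn_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(default_config()), raw)
  class(cfg) <- "canopyn_config"
  validate_config(cfg)
}

#' @rdname read_config
#' @param config A `canopyn_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Validate a pipeline configuration
#'
#' @param config A `canopyn_config` list.
#' @return The config, invisibly, or an error naming the offending field.
#' @export
validate_config <- function(config) {
  bad_alt <- setdiff(config$altitudes, config$allowed_altitudes)
  if (length(bad_alt) > 0) {
    stop_input(sprintf(
      "config field `altitudes`: %s not allowed; allowed altitudes are {%s}.",
      paste(bad_alt, collapse = ", "),
      paste(config$allowed_altitudes, collapse = ", ")
    ))
  }
  if (!config$effect_profile %in% c("table1_calibrated", "flat_null", "linear_dose")) {
    stop_input(sprintf(
      "config field `effect_profile`: unknown profile '%s'.", config$effect_profile
    ))
  }
  if (!config$structural$method %in% c("full", "direct")) {
    stop_input("config field `structural.method` must be 'full' or 'direct'.")
  }
  if (!all(config$models$families %in% c("MLR", "PLSR", "SVR", "RFR"))) {
    stop_input("config field `models.families` has unknown entries.")
  }
  for (f in c("hsi_altitude", "lidar_altitude")) {
    if (!config$fusion[[f]] %in% config$altitudes) {
      stop_input(sprintf("config field `fusion.%s` must be one of `altitudes`.", f))
    }
  }
  invisible(config)
}

config_design <- function(config) {
  do.call(experiment_design, config$design)
}

log_stage <- function(stage, ...) {
  rlang::inform(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the simulation stage
#'
#' Generates the full synthetic bundle (ground truth, spectra per altitude,
#' point clouds) under the configured design and, when `dir` is given, writes
#' it to disk with a manifest.
#'
#' @param config A `canopyn_config`.
#' @param dir Optional output directory.
#' @return The dataset bundle (see [generate_dataset()]).
#' @export
run_simulate <- function(config = default_config(), dir = NULL) {
  validate_config(config)
  t0 <- Sys.time()
  bundle <- generate_dataset(
    design = config_design(config),
    scenes = stats::setNames(
      lapply(config$altitudes, scene_params, allowed = config$allowed_altitudes),
      as.character(config$altitudes)
    ),
    seed = config$seed,
    effect_profile = config$effect_profile,
    cloud_args = config$cloud
  )
  if (!is.null(dir)) {
    write_dataset(bundle, dir)
    write_manifest(config, dir, "simulate")
  }
  log_stage(
    "simulate", "%d trees, %d altitudes (%.1fs)",
    nrow(bundle$ground_truth), length(bundle$spectra),
    as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  bundle
}

#' Run the spectral screening stage
#'
#' Smooths each altitude's spectra (Savitzky-Golay), then screens all NDSI
#' band pairs against each trait, pooled by stage across sites.
#'
#' @param config A `canopyn_config`.
#' @param spectra Named list of wide spectra tibbles keyed by altitude.
#' @param ground_truth Ground-truth tibble.
#' @return A tibble of selected pairs (one row per stage x trait x altitude)
#'   with the score matrices attached as a list column `screen`.
#' @export
run_screen <- function(config, spectra, ground_truth) {
  validate_config(config)
  t0 <- Sys.time()
  combos <- tidyr::expand_grid(
    stage = unique(ground_truth$stage),
    trait = c("cnc", "agna"),
    altitude = as.character(config$altitudes)
  )
  out <- purrr::pmap_dfr(combos, function(stage, trait, altitude) {
    sp <- dplyr::filter(spectra[[altitude]], .data$stage == !!stage)
    sp <- sg_smooth(sp, config$sg$window, config$sg$polyorder)
    gt <- ground_truth[match(sp$sample_id, ground_truth$tree_id), ]
    scr <- band_pair_screen(sp, gt[[trait]],
      stride = config$screen$stride,
      stat = config$screen$stat, trait_label = trait
    )
    sel <- select_best_pair(scr)
    dplyr::mutate(sel,
      stage = stage, altitude = as.numeric(altitude),
      screen = list(scr)
    )
  })
  log_stage(
    "screen", "%d stage x trait x altitude screens (%.1fs)",
    nrow(out), as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  out
}

#' Run the structural extraction stage
#'
#' Extracts PH, CD and CV for every tree cloud. With
#' `structural.method = "full"` each cloud passes through ground
#' classification (progressive TIN densification) and height normalization
#' first; with `"direct"` clouds are taken as already height-normalized
#' (the generator's flat-ground clouds) and only ground-labelled points are
#' dropped.
#'
#' @param config A `canopyn_config`.
#' @param clouds Named list of per-tree clouds.
#' @return A tibble of per-tree metrics.
#' @export
run_structure <- function(config, clouds) {
  validate_config(config)
  t0 <- Sys.time()
  st <- config$structural
  out <- purrr::imap_dfr(clouds, function(cl, id) {
    if (st$method == "full") {
      cls <- classify_ground(cl,
        cell_size = st$cell_size,
        dist_threshold = st$dist_threshold,
        angle_threshold = st$angle_threshold
      )
      cl <- normalize_heights(cls$cloud, cls$ground)
    }
    tree_metrics(cl, tree_id = id)
  })
  log_stage(
    "structure", "%d trees, method=%s (%.1fs)",
    nrow(out), st$method, as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  out
}

#' Run the model-fitting stage
#'
#' For each stage and trait: assembles the fused feature table at the
#' configured altitude pairing and evaluates every configured model family
#' under leave-one-out cross-validation.
#'
#' @param config A `canopyn_config`.
#' @param bundle A dataset bundle (for ground truth and spectra).
#' @param metrics Structural metrics tibble from [run_structure()].
#' @param selections Band-pair selections from [run_screen()].
#' @return A list with `results` (one row per stage x trait x model) and
#'   `cv` (named list of `canopyn_cv` objects).
#' @export
run_fit <- function(config, bundle, metrics, selections) {
  validate_config(config)
  t0 <- Sys.time()
  gt <- bundle$ground_truth
  combos <- tidyr::expand_grid(
    stage = unique(gt$stage), trait = c("cnc", "agna")
  )
  cv_store <- list()
  results <- purrr::pmap_dfr(combos, function(stage, trait) {
    sel <- dplyr::filter(
      selections, .data$stage == !!stage, .data$trait_label == !!trait,
      .data$altitude == config$fusion$hsi_altitude
    )
    if (nrow(sel) != 1) stop_input("no unique band selection for this combo.")
    gt_s <- dplyr::filter(gt, .data$stage == !!stage)
    sp <- sg_smooth(
      dplyr::filter(
        bundle$spectra[[as.character(config$fusion$hsi_altitude)]],
        .data$stage == !!stage
      ),
      config$sg$window, config$sg$polyorder
    )
    feats <- assemble_features(
      gt_s, sp, metrics, sel,
      trait = trait,
      hsi_altitude = config$fusion$hsi_altitude,
      lidar_altitude = config$fusion$lidar_altitude
    )
    purrr::map_dfr(config$models$families, function(fam) {
      spec <- model_spec(fam, seed = derive_seed(
        config$seed, paste("fit", stage, trait, fam)
      ))
      cv <- loocv(feats, spec, repeats = config$models$repeats)
      cv_store[[paste(stage, trait, fam, sep = "_")]] <<- cv
      dplyr::bind_cols(
        tibble::tibble(
          stage = stage, trait = trait, model = fam,
          hsi_altitude = config$fusion$hsi_altitude,
          lidar_altitude = config$fusion$lidar_altitude,
          lambda_i = sel$lambda_i_nm, lambda_j = sel$lambda_j_nm
        ),
        cv$metrics,
        tibble::tibble(
          r2_sd = if (is.null(cv$spread)) 0 else cv$spread$r2,
          rmse_sd = if (is.null(cv$spread)) 0 else cv$spread$rmse
        )
      )
    })
  })
  log_stage(
    "fit", "%d result rows (%.1fs)",
    nrow(results), as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  list(results = results, cv = cv_store)
}

#' Run the whole pipeline
#'
#' simulate -> smooth + screen -> structural extraction -> fused LOOCV
#' comparison. With the default configuration this produces the full results
#' grid: 2 stages x 2 traits x 4 models.
#'
#' @param config A `canopyn_config`.
#' @param dir Optional output directory; when given, `results.csv`,
#'   `predictions.csv`, `selections.csv`, `metrics.csv` and `manifest.json`
#'   are written there.
#' @return A list: `bundle`, `selections`, `metrics`, `results`, `cv`.
#' @export
run_all <- function(config = default_config(), dir = NULL) {
  validate_config(config)
  bundle <- run_simulate(config)
  selections <- run_screen(config, bundle$spectra, bundle$ground_truth)
  metrics <- run_structure(config, bundle$clouds)
  fit <- run_fit(config, bundle, metrics, selections)
  out <- list(
    bundle = bundle, selections = selections, metrics = metrics,
    results = fit$results, cv = fit$cv
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(fit$results, file.path(dir, "results.csv"))
    readr::write_csv(
      purrr::imap_dfr(fit$cv, function(cv, key) {
        dplyr::mutate(cv$predictions, run = key)
      }),
      file.path(dir, "predictions.csv")
    )
    readr::write_csv(
      dplyr::select(selections, -"screen"),
      file.path(dir, "selections.csv")
    )
    readr::write_csv(metrics, file.path(dir, "metrics.csv"))
    write_manifest(config, dir, "run-all")
  }
  out
}

write_manifest <- function(config, dir, stage) {
  manifest <- list(
    stage = stage,
    config = unclass(config),
    package_version = as.character(utils::packageVersion("canopyn")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}
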