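#' Simulate a single-tree LiDAR point cloud
#'
#' Builds a synthetic tree on flat ground: a disc of ground returns at z ~ 0,
#' a thin vertical trunk, and points filling an ellipsoidal crown with
#' horizontal semi-axes `cd / 2` and vertical semi-axis `crown_depth / 2`
#' whose apex touches `z = ph` exactly (a deterministic apex point is always
#' included, so with `jitter_sd = 0` the maximum z equals `ph`).
#'
#' @param ph Plant height in m (> crown_depth).
#' @param cd Crown diameter in m (> 0).
#' @param crown_depth Vertical crown extent in m, `0 < crown_depth < ph`.
#' @param point_density Crown returns per m2 of projected crown area. Zero is
#'   allowed (an empty crown) so downstream degenerate-geometry handling can
#'   be exercised.
#' @param ground_density Ground returns per m2 of the ground disc.
#' @param ground_radius Radius of the ground disc in m (default `cd`).
#' @param trunk_points Number of trunk returns.
#' @param jitter_sd SD (m) of isotropic Gaussian jitter added to all points.
#' @param centre Length-2 numeric, the (x, y) position of the stem.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `x`, `y`, `z` (m) and `part`
#'   (`"ground"`, `"trunk"`, `"crown"`).
#' @export
#'
#' @examples
#' cl <- generate_tree_point_cloud(3, 2, 1.5, seed = 1)
#' max(cl$z)
generate_tree_point_cloud <- function(ph, cd, crown_depth,
                                      point_density = 400,
                                      ground_density = 30,
                                      ground_radius = NULL,
                                      trunk_points = 25,
                                      jitter_sd = 0,
                                      centre = c(0, 0),
                                      seed = 1) {
  assert_scalar_number(ph, "ph", lower = 0, strict_lower = TRUE)
  assert_scalar_number(cd, "cd", lower = 0, strict_lower = TRUE)
  assert_scalar_number(crown_depth, "crown_depth", lower = 0, strict_lower = TRUE)
  if (crown_depth >= ph) stop_input("`crown_depth` must be < `ph`.")
  assert_scalar_number(point_density, "point_density", lower = 0)
  assert_scalar_number(jitter_sd, "jitter_sd", lower = 0)
  if (is.null(ground_radius)) ground_radius <- cd
  a <- cd / 2
  c_ax <- crown_depth / 2
  z_centre <- ph - c_ax
  n_crown <- round(point_density * pi * a^2)
  n_ground <- round(ground_density * pi * ground_radius^2)
  trunk_h <- ph - crown_depth

  pts <- with_seed(derive_seed(seed, "cloud"), {
    # crown: uniform inside the unit ball, scaled to the ellipsoid
    crown <- NULL
    if (n_crown > 0) {
      u <- matrix(rnorm(3 * n_crown), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      r <- runif(n_crown)^(1 / 3)
      crown <- cbind(
        centre[1] + a * r * u[, 1],
        centre[2] + a * r * u[, 2],
        z_centre + c_ax * r * u[, 3]
      )
      crown <- rbind(crown, c(centre[1], centre[2], ph)) # deterministic apex
    }
    trunk <- NULL
    if (trunk_points > 0 && trunk_h > 0) {
      th <- runif(trunk_points, 0, 2 * pi)
      trunk <- cbind(
        centre[1] + 0.03 * cos(th),
        centre[2] + 0.03 * sin(th),
        runif(trunk_points, 0, trunk_h)
      )
    }
    ground <- NULL
    if (n_ground > 0) {
      th <- runif(n_ground, 0, 2 * pi)
      rr <- ground_radius * sqrt(runif(n_ground))
      ground <- cbind(centre[1] + rr * cos(th), centre[2] + rr * sin(th), 0)
    }
    out <- rbind(ground, trunk, crown)
    part <- c(
      rep("ground", NROW(ground)), rep("trunk", NROW(trunk)),
      rep("crown", NROW(crown))
    )
    if (jitter_sd > 0) {
      out <- out + matrix(rnorm(length(out), 0, jitter_sd), ncol = 3)
    }
    list(xyz = out, part = part)
  })
  if (is.null(pts$xyz) || nrow(pts$xyz) == 0) {
    stop_input("generated cloud is empty; increase densities.")
  }
  tibble::tibble(
    x = pts$xyz[, 1], y = pts$xyz[, 2], z = pts$xyz[, 3], part = pts$part
  )
}

#' Simulate a complete multi-sensor dataset
#'
#' Generates, for one trial design: the ground-truth tissue table, a tree
#' layout with structural dimensions allometrically tied to biomass, one
#' reflectance spectrum per tree per flight altitude, and one point cloud per
#' tree. Canopy density (the NIR plateau driver) and the crown dimensions all
#' increase with tree biomass, so structure and spectra carry correlated but
#' distinct nitrogen information.
#'
#' @param design An [experiment_design()].
#' @param scenes Named list of [scene_params()] keyed by altitude, as from
#'   [default_scenes()].
#' @param seed Integer master seed.
#' @param stage Optional single stage to restrict to (`"VGS"` or `"FES"`).
#' @param effect_profile Passed to [generate_ground_truth()].
#' @param cloud_args Named list of overrides for
#'   [generate_tree_point_cloud()] (e.g. `point_density`).
#'
#' @return A list of class `canopyn_dataset` with elements `ground_truth`,
#'   `layout` (tree_id, x, y, ph, cd, crown_depth, canopy_density), `spectra`
#'   (named list of wide tibbles, one per altitude), `clouds` (named list of
#'   point-cloud tibbles keyed by tree_id), `design`, `scenes`, `seed`.
#' @export
generate_dataset <- function(design = experiment_design(),
                             scenes = default_scenes(),
                             seed = 1,
                             stage = NULL,
                             effect_profile = "table1_calibrated",
                             cloud_args = list()) {
  if (!is.null(stage)) {
    design <- experiment_design(
      sites = design$sites, stages = stage, n_rates = design$n_rates,
      replicates = design$replicates, trees_per_cell = design$trees_per_cell
    )
  }
  gt <- generate_ground_truth(design, effect_profile, seed = seed)
  layout <- tree_layout(gt, seed = seed)

  spectra <- lapply(scenes, function(scene) {
    refl <- t(vapply(seq_len(nrow(gt)), function(i) {
      spectrum_vector(
        gt$cnc[i], layout$canopy_density[i], scene,
        seed = derive_seed(seed, paste("spec", gt$tree_id[i], scene$altitude))
      )
    }, numeric(length(scene$grid))))
    colnames(refl) <- band_names(scene$grid)
    dplyr::bind_cols(
      tibble::tibble(
        sample_id = gt$tree_id, site = gt$site, stage = gt$stage,
        altitude = scene$altitude
      ),
      tibble::as_tibble(refl)
    )
  })
  names(spectra) <- vapply(scenes, function(s) as.character(s$altitude), character(1))

  clouds <- lapply(seq_len(nrow(gt)), function(i) {
    args <- utils::modifyList(
      list(
        ph = layout$ph[i], cd = layout$cd[i],
        crown_depth = layout$crown_depth[i],
        seed = derive_seed(seed, paste("cloud", gt$tree_id[i]))
      ),
      cloud_args
    )
    do.call(generate_tree_point_cloud, args)
  })
  names(clouds) <- gt$tree_id

  structure(
    list(
      ground_truth = gt, layout = layout, spectra = spectra,
      clouds = clouds, design = design, scenes = scenes, seed = seed
    ),
    class = "canopyn_dataset"
  )
}

# Allometry: crown dimensions and canopy density track biomass, with small
# lognormal-ish noise. Tuned to 8-year orchard trees at 2 x 3 m spacing.
tree_layout <- function(gt, seed) {
  n <- nrow(gt)
  noise <- with_seed(derive_seed(seed, "layout"), {
    list(
      ph = rnorm(n, 0, 0.05), cd = rnorm(n, 0, 0.04),
      depth = rnorm(n, 0, 0.03)
    )
  })
  ph <- pmax(1.2, 1.6 + 0.45 * gt$biomass + noise$ph)
  cd <- pmax(0.8, 1.1 + 0.35 * gt$biomass + noise$cd)
  crown_depth <- pmin(pmax(0.6, 0.5 * ph + noise$depth), ph - 0.2)
  idx <- seq_len(n) - 1
  tibble::tibble(
    tree_id = gt$tree_id,
    x = 3 * (idx %% 8), y = 2 * (idx %/% 8),
    ph = ph, cd = cd, crown_depth = crown_depth,
    canopy_density = pmin(0.95, pmax(0.35, 0.35 + 0.13 * gt$biomass))
  )
}

#' Write / read a simulated dataset bundle
#'
#' `write_dataset()` lays a bundle out as plain-text files: `ground_truth.csv`,
#' `layout.csv`, one `spectra_<altitude>.csv` per altitude, and one ASCII XYZ
#' file per tree under `clouds/`. `read_dataset()` reads such a directory back
#' into the in-memory structure.
#'
#' @param bundle A `canopyn_dataset` from [generate_dataset()].
#' @param dir Directory to write into / read from.
#'
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()` returns
#'   a list with `ground_truth`, `layout`, `spectra`, `clouds`.
#' @export
write_dataset <- function(bundle, dir) {
  if (!inherits(bundle, "canopyn_dataset")) {
    stop_input("`bundle` must come from generate_dataset().")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(bundle$ground_truth, file.path(dir, "ground_truth.csv"))
  readr::write_csv(bundle$layout, file.path(dir, "layout.csv"))
  for (alt in names(bundle$spectra)) {
    readr::write_csv(
      bundle$spectra[[alt]],
      file.path(dir, sprintf("spectra_%s.csv", alt))
    )
  }
  cdir <- file.path(dir, "clouds")
  dir.create(cdir, showWarnings = FALSE)
  for (id in names(bundle$clouds)) {
    cl <- bundle$clouds[[id]]
    writeLines(
      sprintf("%.6f %.6f %.6f", cl$x, cl$y, cl$z),
      file.path(cdir, paste0(id, ".xyz"))
    )
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  need <- file.path(dir, c("ground_truth.csv", "layout.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0) {
    stop_input(sprintf("missing dataset file(s): %s", paste(missing, collapse = ", ")))
  }
  spectra_files <- list.files(dir, "^spectra_[0-9]+\\.csv$", full.names = TRUE)
  spectra <- lapply(spectra_files, function(f) {
    readr::read_csv(f, show_col_types = FALSE)
  })
  names(spectra) <- sub("^spectra_([0-9]+)\\.csv$", "\\1", basename(spectra_files))
  cloud_files <- list.files(file.path(dir, "clouds"), "\\.xyz$", full.names = TRUE)
  clouds <- lapply(cloud_files, read_xyz)
  names(clouds) <- sub("\\.xyz$", "", basename(cloud_files))
  list(
    ground_truth = readr::read_csv(file.path(dir, "ground_truth.csv"),
      show_col_types = FALSE
    ),
    layout = readr::read_csv(file.path(dir, "layout.csv"), show_col_types = FALSE),
    spectra = spectra,
    clouds = clouds
  )
}

#' Read an ASCII XYZ point cloud
#'
#' @param path Path to a whitespace-separated `x y z` file (metres).
#' @return A tibble with columns `x`, `y`, `z`.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("no such file: %s", path))
  m <- as.matrix(utils::read.table(path,
    col.names = c("x", "y", "z"),
    colClasses = "numeric"
  ))
  tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3])
}
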