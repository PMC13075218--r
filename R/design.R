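#' Define a fertilization-trial design
#'
#' Describes the factorial layout the synthetic-data generator emulates: a
#' randomized complete block trial with two orchard sites, two phenological
#' stages (vigorous vegetative growth, VGS; fruit expansion, FES), four
#' nitrogen application rates and three replicate blocks per rate, each block
#' contributing `trees_per_cell` sampled trees.
#'
#' @param sites Character vector of site labels.
#' @param stages Character vector of stages, a subset of `c("VGS", "FES")`.
#' @param n_rates Applied nitrogen rates in kg N ha-1, non-negative and
#'   strictly increasing. Rate labels `N0, N1, ...` follow the order.
#' @param replicates Replicate blocks per site x stage x rate cell.
#' @param trees_per_cell Trees sampled per replicate block.
#'
#' @return An object of class `experiment_design`.
#' @export
#'
#' @examples
#' d <- experiment_design()
#' d$n_rates
experiment_design <- function(sites = c("Lishi", "Ciyun"),
                              stages = c("VGS", "FES"),
                              n_rates = c(0, 150, 300, 450),
                              replicates = 3,
                              trees_per_cell = 4) {
  if (length(sites) < 1 || anyDuplicated(sites)) stop_input("invalid `sites`.")
  if (!all(stages %in% c("VGS", "FES")) || length(stages) < 1) {
    stop_input("`stages` must be a subset of c(\"VGS\", \"FES\").")
  }
  if (any(n_rates < 0) || is.unsorted(n_rates, strictly = TRUE)) {
    stop_input("`n_rates` must be non-negative and strictly increasing.")
  }
  assert_scalar_number(replicates, "replicates", lower = 1)
  assert_scalar_number(trees_per_cell, "trees_per_cell", lower = 1)
  structure(
    list(
      sites = sites, stages = stages, n_rates = n_rates,
      rate_labels = paste0("N", seq_along(n_rates) - 1),
      replicates = as.integer(replicates),
      trees_per_cell = as.integer(trees_per_cell)
    ),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "Trial design: %d site(s) x %d stage(s) x %d N rate(s) x %d replicate(s) x %d tree(s)\n",
    length(x$sites), length(x$stages), length(x$n_rates),
    x$replicates, x$trees_per_cell
  ))
  invisible(x)
}

#' Reference treatment summary used for generator calibration
#'
#' Group means and standard deviations of biomass (kg plant-1), CNC (g kg-1)
#' and AGNA (g plant-1) for every site x stage x nitrogen-rate cell of the
#' two-site field trial the generator emulates (n = 3 replicate blocks per
#' cell). The `table1_calibrated` profile of [generate_ground_truth()] draws
#' trees so that each cell's tree-level distribution has these moments.
#'
#' @return A tibble with columns site, stage, variable, rate_label, mean, sd.
#' @export
nitrogen_reference_summary <- function() {
  cell <- function(site, stage, variable, means, sds) {
    tibble::tibble(
      site = site, stage = stage, variable = variable,
      rate_label = paste0("N", 0:3), mean = means, sd = sds
    )
  }
  dplyr::bind_rows(
    cell("Lishi", "VGS", "biomass", c(1.38, 1.86, 1.91, 2.73), c(0.05, 0.15, 0.18, 0.16)),
    cell("Ciyun", "VGS", "biomass", c(2.81, 3.18, 3.89, 4.08), c(0.12, 0.09, 0.05, 0.10)),
    cell("Lishi", "VGS", "cnc", c(38.06, 38.86, 39.35, 39.95), c(0.73, 1.25, 1.06, 1.38)),
    cell("Ciyun", "VGS", "cnc", c(32.19, 32.48, 33.02, 33.58), c(0.53, 0.39, 0.33, 0.72)),
    cell("Lishi", "VGS", "agna", c(17.70, 24.48, 26.61, 37.12), c(2.58, 0.21, 1.10, 0.76)),
    cell("Ciyun", "VGS", "agna", c(24.44, 32.06, 40.53, 49.15), c(1.52, 1.00, 1.75, 4.10)),
    cell("Lishi", "FES", "biomass", c(2.58, 2.69, 2.81, 2.87), c(0.12, 0.16, 0.12, 0.18)),
    cell("Ciyun", "FES", "biomass", c(3.68, 3.74, 3.98, 4.12), c(0.18, 0.10, 0.18, 0.32)),
    cell("Lishi", "FES", "cnc", c(32.58, 35.62, 39.76, 38.54), c(0.31, 0.63, 1.28, 0.56)),
    cell("Ciyun", "FES", "cnc", c(22.63, 28.00, 35.41, 32.35), c(1.23, 1.24, 1.26, 1.11)),
    cell("Lishi", "FES", "agna", c(32.65, 38.24, 47.18, 41.63), c(3.80, 0.98, 2.30, 1.75)),
    cell("Ciyun", "FES", "agna", c(32.89, 40.15, 59.92, 51.51), c(1.15, 3.24, 3.09, 3.22))
  )
}

# Stage-specific organ dry-mass fractions (leaf/shoot/fruit/trunk). Chosen so
# that for every calibration cell the leaf nitrogen stock alone stays safely
# below the AGNA target, leaving positive concentrations for the other organs.
organ_fractions <- function(stage) {
  switch(stage,
    VGS = c(leaf = 0.20, shoot = 0.30, fruit = 0.00, trunk = 0.50),
    FES = c(leaf = 0.25, shoot = 0.20, fruit = 0.15, trunk = 0.40),
    stop_input(sprintf("unknown stage '%s'.", stage))
  )
}

# Relative nitrogen-concentration weights used to split the non-leaf nitrogen
# stock across shoot, fruit and trunk (fruit richest, trunk poorest).
organ_nc_weights <- c(shoot = 0.55, fruit = 0.85, trunk = 0.20)
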