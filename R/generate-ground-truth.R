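#' Simulate a ground-truth tissue table
#'
#' Draws per-tree organ dry masses and nitrogen concentrations for every cell
#' of a trial design, then derives biomass, CNC and AGNA through [cnc()] and
#' [agna()] so the stored aggregates are always internally consistent.
#'
#' Profiles:
#' \describe{
#'   \item{`table1_calibrated`}{Each site x stage x rate cell draws trees iid
#'     so that the implied biomass, CNC and AGNA distributions match the
#'     reference summary of [nitrogen_reference_summary()]: biomass and CNC
#'     are sampled directly from the cell's normal law; the remaining
#'     (non-leaf) nitrogen stock is allocated across shoot, fruit and trunk
#'     with fixed concentration weights so AGNA hits its own cell law.}
#'   \item{`flat_null`}{All rates within a site x stage share one
#'     distribution (the across-rate mean of means and SDs), giving an
#'     expected between-rate ANOVA F near 1.}
#'   \item{`linear_dose`}{Cell means interpolate linearly in applied N
#'     between the calibrated N0 and top-rate means.}
#' }
#'
#' @param design An [experiment_design()].
#' @param effect_profile One of `"table1_calibrated"`, `"flat_null"`,
#'   `"linear_dose"`.
#' @param seed Integer master seed; the same seed reproduces the table
#'   byte for byte.
#'
#' @return A tibble with one row per tree: tree_id, site, stage, n_rate,
#'   rate_label, replicate, organ masses `m_leaf` ... `m_trunk`
#'   (kg plant-1), organ concentrations `nc_leaf` ... `nc_trunk` (g kg-1),
#'   `biomass` (kg plant-1), `cnc` (g kg-1) and `agna` (g plant-1).
#' @export
#'
#' @examples
#' gt <- generate_ground_truth(experiment_design(), seed = 1)
#' dplyr::count(gt, site, stage)
generate_ground_truth <- function(design = experiment_design(),
                                  effect_profile = c(
                                    "table1_calibrated",
                                    "flat_null", "linear_dose"
                                  ),
                                  seed = 1) {
  if (!inherits(design, "experiment_design")) {
    stop_input("`design` must come from experiment_design().")
  }
  effect_profile <- match.arg(effect_profile)
  if (design$replicates < 1) stop_input("replicates must be positive.")

  targets <- profile_targets(design, effect_profile)
  cells <- tidyr::expand_grid(
    site = design$sites, stage = design$stages,
    rate_label = design$rate_labels
  )
  rate_of <- stats::setNames(design$n_rates, design$rate_labels)

  rows <- purrr::pmap_dfr(cells, function(site, stage, rate_label) {
    tg <- dplyr::filter(
      targets, .data$site == !!site, .data$stage == !!stage,
      .data$rate_label == !!rate_label
    )
    mu <- stats::setNames(tg$mean, tg$variable)
    sg <- stats::setNames(tg$sd, tg$variable)
    n_tree <- design$replicates * design$trees_per_cell
    cell_seed <- derive_seed(seed, paste("gt", site, stage, rate_label))
    draw <- with_seed(cell_seed, {
      list(
        biomass = pmax(0.2, rnorm(n_tree, mu["biomass"], sg["biomass"])),
        cnc = pmax(1, rnorm(n_tree, mu["cnc"], sg["cnc"])),
        agna = rnorm(n_tree, mu["agna"], sg["agna"])
      )
    })
    fr <- organ_fractions(stage)
    masses <- outer(draw$biomass, fr) # trees x 4 organs
    colnames(masses) <- names(fr)
    # Non-leaf nitrogen stock; floored at 2% of the AGNA draw so that extreme
    # tail draws cannot imply negative organ concentrations.
    resid <- pmax(draw$agna - draw$cnc * masses[, "leaf"], 0.02 * abs(draw$agna))
    w <- organ_nc_weights
    denom <- masses[, "shoot"] * w["shoot"] + masses[, "fruit"] * w["fruit"] +
      masses[, "trunk"] * w["trunk"]
    x <- resid / denom
    tibble::tibble(
      site = site, stage = stage,
      n_rate = unname(rate_of[rate_label]), rate_label = rate_label,
      replicate = rep(seq_len(design$replicates), each = design$trees_per_cell),
      tree_in_rep = rep(seq_len(design$trees_per_cell), design$replicates),
      m_leaf = masses[, "leaf"], m_shoot = masses[, "shoot"],
      m_fruit = masses[, "fruit"], m_trunk = masses[, "trunk"],
      nc_leaf = draw$cnc,
      nc_shoot = x * w["shoot"],
      nc_fruit = ifelse(masses[, "fruit"] > 0, x * w["fruit"], 0),
      nc_trunk = x * w["trunk"]
    )
  })

  rows <- dplyr::mutate(rows,
    tree_id = sprintf(
      "%s_%s_%s_r%d_t%d", .data$site, .data$stage,
      .data$rate_label, .data$replicate, .data$tree_in_rep
    )
  )
  # Aggregates always recomputed through the nitrogen module.
  agg <- purrr::pmap_dfr(
    rows[, c("m_leaf", "m_shoot", "m_fruit", "m_trunk",
             "nc_leaf", "nc_shoot", "nc_fruit", "nc_trunk")],
    function(m_leaf, m_shoot, m_fruit, m_trunk,
             nc_leaf, nc_shoot, nc_fruit, nc_trunk) {
      organs <- tibble::tibble(
        organ = c("leaf", "shoot", "fruit", "trunk"),
        nc = c(nc_leaf, nc_shoot, nc_fruit, nc_trunk),
        mass = c(m_leaf, m_shoot, m_fruit, m_trunk)
      )
      tibble::tibble(
        biomass = sum(organs$mass), cnc = cnc(organs), agna = agna(organs)
      )
    }
  )
  dplyr::select(
    dplyr::bind_cols(rows, agg),
    "tree_id", "site", "stage", "n_rate", "rate_label", "replicate",
    dplyr::starts_with("m_"), dplyr::starts_with("nc_"),
    "biomass", "cnc", "agna"
  )
}

profile_targets <- function(design, effect_profile) {
  ref <- nitrogen_reference_summary()
  missing_cells <- setdiff(design$sites, unique(ref$site))
  if (length(missing_cells) > 0) {
    stop_input(sprintf(
      "no calibration reference for site(s): %s",
      paste(missing_cells, collapse = ", ")
    ))
  }
  k <- length(design$n_rates)
  ref_rates <- paste0("N", 0:3)
  if (effect_profile == "table1_calibrated") {
    if (k != 4) {
      stop_input("table1_calibrated requires the four reference N rates.")
    }
    out <- dplyr::filter(ref, .data$stage %in% design$stages, .data$site %in% design$sites)
    return(out)
  }
  base <- dplyr::summarise(
    dplyr::group_by(ref, .data$site, .data$stage, .data$variable),
    m0 = .data$mean[.data$rate_label == "N0"],
    m3 = .data$mean[.data$rate_label == ref_rates[length(ref_rates)]],
    mean_all = mean(.data$mean), sd_all = mean(.data$sd),
    .groups = "drop"
  )
  base <- dplyr::filter(base, .data$stage %in% design$stages, .data$site %in% design$sites)
  max_rate <- max(design$n_rates)
  purrr::pmap_dfr(base, function(site, stage, variable, m0, m3, mean_all, sd_all) {
    mu <- if (effect_profile == "flat_null") {
      rep(mean_all, k)
    } else { # linear_dose
      m0 + (m3 - m0) * design$n_rates / max(max_rate, 1)
    }
    tibble::tibble(
      site = site, stage = stage, variable = variable,
      rate_label = design$rate_labels, mean = mu, sd = sd_all
    )
  })
}

#' Subsample trees the way the destructive field campaign did
#'
#' Field campaigns cannot fell every tree: per growth stage, two trees per
#' site x nitrogen-rate cell were destructively sampled (16 trees per stage).
#' This helper draws that subset from a generated ground-truth table.
#'
#' @param ground_truth A tibble from [generate_ground_truth()].
#' @param per_cell Trees sampled per site x stage x rate cell.
#' @param seed Integer seed for the draw.
#'
#' @return The subsampled ground-truth tibble.
#' @export
sample_study_trees <- function(ground_truth, per_cell = 2, seed = 1) {
  assert_scalar_number(per_cell, "per_cell", lower = 1)
  picks <- ground_truth |>
    dplyr::group_by(.data$site, .data$stage, .data$rate_label) |>
    dplyr::group_map(function(g, key) {
      if (nrow(g) < per_cell) {
        stop_input("not enough trees in a cell to subsample.")
      }
      idx <- with_seed(
        derive_seed(seed, paste("study", key$site, key$stage, key$rate_label)),
        sample.int(nrow(g), per_cell)
      )
      g$tree_id[idx]
    })
  dplyr::filter(ground_truth, .data$tree_id %in% unlist(picks))
}
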