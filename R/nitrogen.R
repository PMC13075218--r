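#' Canopy nitrogen concentration from organ samples
#'
#' The canopy nitrogen concentration (CNC, g kg-1) of a tree is defined as the
#' nitrogen concentration of its leaves, the organ that dominates the canopy
#' optical signal.
#'
#' @param organs A data frame with one row per organ and columns `organ`
#'   (one of `"leaf"`, `"shoot"`, `"fruit"`, `"trunk"`), `nc` (nitrogen
#'   concentration, g kg-1) and `mass` (dry mass, kg plant-1).
#'
#' @return CNC in g kg-1 (a single number).
#' @export
#'
#' @examples
#' organs <- tibble::tibble(
#'   organ = c("leaf", "shoot", "fruit", "trunk"),
#'   nc = c(30, 20, 25, 10), mass = c(0.5, 0.4, 0.2, 1.0)
#' )
#' cnc(organs) # 30
#' agna(organs) # 38
cnc <- function(organs) {
  organs <- check_organs(organs, require_all = FALSE)
  leaf <- organs$nc[organs$organ == "leaf"]
  if (length(leaf) != 1) stop_input("`organs` must contain exactly one leaf row.")
  leaf
}

#' Aboveground nitrogen accumulation from organ samples
#'
#' AGNA (g plant-1) sums, over the four aboveground organs (leaf, shoot,
#' fruit, trunk), the product of organ nitrogen concentration (g kg-1) and
#' organ dry mass (kg plant-1). Each organ's nitrogen stock uses its own dry
#' mass; a zero fruit mass (pre-fruiting stages) simply contributes nothing.
#'
#' @inheritParams cnc
#'
#' @return AGNA in g plant-1 (a single number).
#' @export
agna <- function(organs) {
  organs <- check_organs(organs, require_all = TRUE)
  sum(organs$nc * organs$mass)
}

check_organs <- function(organs, require_all = TRUE) {
  if (!is.data.frame(organs) || !all(c("organ", "nc", "mass") %in% names(organs))) {
    stop_input("`organs` must be a data frame with columns organ, nc, mass.")
  }
  known <- c("leaf", "shoot", "fruit", "trunk")
  if (!all(organs$organ %in% known)) {
    stop_input(sprintf(
      "unknown organ(s): %s",
      paste(setdiff(organs$organ, known), collapse = ", ")
    ))
  }
  if (any(!is.finite(organs$nc)) || any(!is.finite(organs$mass)) ||
    any(organs$nc < 0) || any(organs$mass < 0)) {
    stop_input("organ `nc` and `mass` must be finite and non-negative.")
  }
  if (require_all && !setequal(unique(organs$organ), known)) {
    stop_input(sprintf(
      "all four organs are required; missing: %s",
      paste(setdiff(known, organs$organ), collapse = ", ")
    ))
  }
  if (anyDuplicated(organs$organ)) stop_input("duplicated organ rows.")
  organs
}

#' One-way analysis of variance
#'
#' Classic fixed-effects one-way ANOVA across treatment groups, as used to
#' test nitrogen-rate effects on biomass, CNC and AGNA.
#'
#' @param groups A list of numeric vectors (one per group), or a data frame
#'   with columns `value` and `group`.
#'
#' @return An object of class `canopyn_anova` with elements `f`, `df_between`,
#'   `df_within`, `p_value`, `group_means`, `ss_between`, `ss_within`.
#'   [tidy()] and [glance()] methods are available.
#' @export
#'
#' @examples
#' anova_oneway(list(a = c(1, 2, 3), b = c(4, 5, 6)))$f # 13.5
anova_oneway <- function(groups) {
  df <- groups_to_df(groups)
  k <- nlevels(df$group)
  if (k < 2) stop_input("need at least 2 groups.")
  if (any(table(df$group) < 2)) stop_input("each group needs n >= 2.")
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  res <- list(
    f = tab[["F value"]][1],
    df_between = tab[["Df"]][1],
    df_within = tab[["Df"]][2],
    p_value = tab[["Pr(>F)"]][1],
    group_means = tapply(df$value, df$group, mean),
    group_ns = as.integer(table(df$group)),
    ss_between = tab[["Sum Sq"]][1],
    ss_within = tab[["Sum Sq"]][2],
    fit = fit
  )
  class(res) <- "canopyn_anova"
  res
}

groups_to_df <- function(groups) {
  if (is.data.frame(groups)) {
    if (!all(c("value", "group") %in% names(groups))) {
      stop_input("data frame input needs columns `value` and `group`.")
    }
    df <- data.frame(value = groups$value, group = factor(groups$group))
  } else if (is.list(groups)) {
    if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
    df <- data.frame(
      value = unlist(groups, use.names = FALSE),
      group = factor(rep(names(groups), lengths(groups)), levels = names(groups))
    )
  } else {
    stop_input("`groups` must be a list of numeric vectors or a data frame.")
  }
  if (!is.numeric(df$value) || any(!is.finite(df$value))) {
    stop_input("group values must be finite numbers.")
  }
  df
}

#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the between/within sum-of-squares decomposition from group
#' means, standard deviations and sizes. Identical to [anova_oneway()] applied
#' to any raw data with the same first two moments, which makes published
#' mean +- SD tables directly testable.
#'
#' @param means,sds,ns Equal-length numeric vectors of group means, standard
#'   deviations and sizes (all `ns >= 2`).
#'
#' @return A `canopyn_anova` object (see [anova_oneway()]).
#' @export
#'
#' @examples
#' anova_from_summary(c(2, 5), c(1, 1), c(3, 3))$f # 13.5
anova_from_summary <- function(means, sds, ns) {
  if (length(means) != length(sds) || length(means) != length(ns)) {
    stop_input("`means`, `sds` and `ns` must have equal length.")
  }
  if (length(means) < 2) stop_input("need at least 2 groups.")
  if (any(ns < 2)) stop_input("all `ns` must be >= 2.")
  if (any(!is.finite(means)) || any(!is.finite(sds)) || any(sds < 0)) {
    stop_input("`means` and `sds` must be finite, sds non-negative.")
  }
  n_tot <- sum(ns)
  grand <- sum(ns * means) / n_tot
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  dfb <- length(means) - 1
  dfw <- n_tot - length(means)
  msw <- ssw / dfw
  f <- if (msw == 0) {
    if (ssb == 0) 0 else Inf
  } else {
    (ssb / dfb) / msw
  }
  res <- list(
    f = f, df_between = dfb, df_within = dfw,
    p_value = stats::pf(f, dfb, dfw, lower.tail = FALSE),
    group_means = stats::setNames(means, names(means)),
    group_ns = as.integer(ns),
    ss_between = ssb, ss_within = ssw, fit = NULL
  )
  class(res) <- "canopyn_anova"
  res
}

#' @export
print.canopyn_anova <- function(x, ...) {
  cat(sprintf(
    "One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
    x$df_between, x$df_within, x$f, x$p_value
  ))
  invisible(x)
}

#' Tukey HSD comparisons with a compact letter display
#'
#' Runs Tukey's honestly-significant-difference test on all group pairs and
#' summarises it as a compact letter display: groups sharing a letter are not
#' significantly different at level `alpha`. Letters are assigned by an
#' insert-and-absorb sweep over groups ordered by descending mean, so the
#' highest-mean group always carries `"a"`.
#'
#' @inheritParams anova_oneway
#' @param alpha Significance level for the pairwise comparisons.
#'
#' @return A list with `pairwise` (tibble of pairs with adjusted p-values),
#'   `letters` (tibble of group, mean, letters) and `alpha`.
#' @export
tukey_letters <- function(groups, alpha = 0.05) {
  df <- groups_to_df(groups)
  if (nlevels(df$group) < 2) stop_input("need at least 2 groups.")
  if (any(table(df$group) < 2)) stop_input("each group needs n >= 2.")
  fit <- stats::aov(value ~ group, data = df)
  tk <- stats::TukeyHSD(fit)$group
  pairs <- tibble::tibble(
    pair = rownames(tk),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"]
  )
  lev <- levels(df$group)
  k <- length(lev)
  sig <- matrix(FALSE, k, k, dimnames = list(lev, lev))
  for (r in seq_len(nrow(pairs))) {
    ab <- strsplit(pairs$pair[r], "-", fixed = TRUE)[[1]]
    sig[ab[1], ab[2]] <- sig[ab[2], ab[1]] <- pairs$p_adj[r] < alpha
  }
  means <- tapply(df$value, df$group, mean)
  letters_vec <- cld_letters(sig, order(means, decreasing = TRUE))
  list(
    pairwise = pairs,
    letters = tibble::tibble(
      group = lev, mean = as.numeric(means),
      letters = letters_vec
    )[order(means, decreasing = TRUE), ],
    alpha = alpha
  )
}

# Insert-and-absorb compact letter display from a logical significance matrix.
# `ord` gives the group order that receives letters first.
cld_letters <- function(sig, ord) {
  k <- nrow(sig)
  sets <- list()
  for (g in ord) {
    placed <- FALSE
    for (s in seq_along(sets)) {
      if (all(!sig[g, sets[[s]]])) {
        sets[[s]] <- c(sets[[s]], g)
        placed <- TRUE
      }
    }
    if (!placed) {
      new_set <- g
      for (h in ord) {
        if (h != g && !sig[g, h] && all(!sig[h, new_set])) {
          new_set <- c(new_set, h)
        }
      }
      sets[[length(sets) + 1]] <- new_set
    }
  }
  # drop sets fully contained in another
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i != j && keep[j] && all(sets[[i]] %in% sets[[j]]) &&
        length(sets[[i]]) < length(sets[[j]])) {
        keep[i] <- FALSE
      }
    }
  }
  sets <- sets[keep]
  out <- character(k)
  for (s in seq_along(sets)) {
    out[sets[[s]]] <- paste0(out[sets[[s]]], letters[s])
  }
  unname(vapply(
    out, function(x) paste(sort(strsplit(x, "")[[1]]), collapse = ""),
    character(1)
  ))
}

#' Treatment-effect summary of a ground-truth table
#'
#' Per site, stage and variable (biomass, CNC, AGNA), summarises each nitrogen
#' rate as mean +- SD, runs the one-way ANOVA across rates and attaches
#' Tukey compact letters - the layout of a standard fertilization-trial
#' summary table.
#'
#' @param ground_truth A ground-truth tibble from [generate_ground_truth()].
#' @param alpha Significance level for the letter display.
#'
#' @return A tibble with columns site, stage, variable, rate_label, mean, sd,
#'   n, letters, p_value.
#' @export
treatment_summary <- function(ground_truth, alpha = 0.05) {
  vars <- c(biomass = "biomass", cnc = "cnc", agna = "agna")
  combos <- dplyr::distinct(ground_truth, .data$site, .data$stage)
  purrr::pmap_dfr(combos, function(site, stage) {
    sub <- dplyr::filter(ground_truth, .data$site == !!site, .data$stage == !!stage)
    purrr::imap_dfr(vars, function(col, var) {
      groups <- split(sub[[col]], sub$rate_label)
      an <- anova_oneway(groups)
      tl <- tukey_letters(groups, alpha = alpha)
      letters_map <- stats::setNames(tl$letters$letters, tl$letters$group)
      tibble::tibble(
        site = site, stage = stage, variable = var,
        rate_label = names(groups),
        mean = vapply(groups, mean, numeric(1)),
        sd = vapply(groups, stats::sd, numeric(1)),
        n = lengths(groups),
        letters = unname(letters_map[names(groups)]),
        p_value = an$p_value
      )
    })
  })
}
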