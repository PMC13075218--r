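#' Assemble the fused feature table for one trait
#'
#' Joins, per tree: the NDSI value at a selected band pair computed from the
#' chosen hyperspectral altitude's spectra, the LiDAR structural triplet
#' (PH, CD, CV) from the chosen LiDAR altitude, and the ground-truth target
#' (CNC or AGNA). The two sensor altitudes are independent - the optimized
#' configuration pairs low-altitude LiDAR with high-altitude spectra.
#'
#' @param ground_truth Ground-truth tibble with `tree_id` and the trait
#'   column.
#' @param spectra Wide spectra tibble for the HSI altitude (or a named list
#'   keyed by altitude, from which `hsi_altitude` selects).
#' @param metrics Structural metrics tibble (`tree_id`, `ph`, `cd`, `cv`).
#' @param selection A band-pair selection row from [select_best_pair()] (or
#'   any list with `lambda_i`, `lambda_j`).
#' @param trait `"cnc"` or `"agna"` (a column of `ground_truth`).
#' @param hsi_altitude,lidar_altitude Altitudes (m) recorded as provenance;
#'   `hsi_altitude` also selects from a spectra list.
#'
#' @return A tibble (`tree_id`, `ndsi`, `ph`, `cd`, `cv`, `target`) with a
#'   `provenance` attribute. One row per tree; any tree missing from a source
#'   is an error naming the ids.
#' @export
assemble_features <- function(ground_truth, spectra, metrics, selection,
                              trait = c("cnc", "agna"),
                              hsi_altitude = NA, lidar_altitude = NA) {
  trait <- match.arg(trait)
  if (is.list(spectra) && !is.data.frame(spectra)) {
    key <- as.character(hsi_altitude)
    if (!key %in% names(spectra)) {
      stop_input(sprintf("no spectra for altitude '%s'.", key))
    }
    spectra <- spectra[[key]]
  }
  if (!"tree_id" %in% names(ground_truth) || !trait %in% names(ground_truth)) {
    stop_input(sprintf("`ground_truth` needs columns tree_id and %s.", trait))
  }
  ids <- ground_truth$tree_id
  missing_sp <- setdiff(ids, spectra$sample_id)
  if (length(missing_sp) > 0) {
    stop_input(sprintf(
      "tree(s) missing from spectra: %s",
      paste(utils::head(missing_sp, 5), collapse = ", ")
    ))
  }
  missing_mt <- setdiff(ids, metrics$tree_id)
  if (length(missing_mt) > 0) {
    stop_input(sprintf(
      "tree(s) missing from structural metrics: %s",
      paste(utils::head(missing_mt, 5), collapse = ", ")
    ))
  }
  sp <- spectra[match(ids, spectra$sample_id), ]
  nd <- ndsi(sp, selection$lambda_i, selection$lambda_j)
  mt <- metrics[match(ids, metrics$tree_id), ]
  out <- tibble::tibble(
    tree_id = ids, ndsi = nd,
    ph = mt$ph, cd = mt$cd, cv = mt$cv,
    target = ground_truth[[trait]]
  )
  if (any(!stats::complete.cases(out))) {
    stop_input("feature table has missing cells.")
  }
  attr(out, "provenance") <- list(
    trait = trait, hsi_altitude = hsi_altitude, lidar_altitude = lidar_altitude,
    lambda_i = selection$lambda_i, lambda_j = selection$lambda_j
  )
  out
}

#' Specify a regression model family
#'
#' The four families compared for nitrogen retrieval. Defaults: PLSR uses 2
#' latent components; SVR uses an RBF kernel with `cost = 10`,
#' `epsilon = 0.1` and gamma `1 / (p * var)` on training-standardized
#' predictors; RFR uses 100 trees, minimum split size 2, minimum leaf size 2
#' and maximum depth 3.
#'
#' @param family `"MLR"`, `"PLSR"`, `"SVR"` or `"RFR"`.
#' @param ncomp PLSR latent components.
#' @param cost,epsilon,gamma SVR hyperparameters (`gamma = NULL` for the
#'   variance-scaled default).
#' @param num_trees,min_split,min_leaf,max_depth RFR hyperparameters.
#' @param seed Seed for stochastic families.
#'
#' @return An object of class `canopyn_model_spec`.
#' @export
model_spec <- function(family = c("MLR", "PLSR", "SVR", "RFR"),
                       ncomp = 2,
                       cost = 10, epsilon = 0.1, gamma = NULL,
                       num_trees = 100, min_split = 2, min_leaf = 2,
                       max_depth = 3,
                       seed = 1) {
  family <- match.arg(family)
  structure(
    list(
      family = family, ncomp = ncomp, cost = cost, epsilon = epsilon,
      gamma = gamma, num_trees = num_trees, min_split = min_split,
      min_leaf = min_leaf, max_depth = max_depth, seed = seed
    ),
    class = "canopyn_model_spec"
  )
}

is_stochastic <- function(spec) spec$family == "RFR"

#' Fit a regression model
#'
#' @param spec A [model_spec()].
#' @param x Predictor matrix or data frame (numeric columns).
#' @param y Numeric response.
#'
#' @return An object of class `canopyn_model` usable with [predict_model()].
#' @export
fit_model <- function(spec, x, y) {
  if (!inherits(spec, "canopyn_model_spec")) {
    stop_input("`spec` must come from model_spec().")
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) != length(y)) stop_input("nrow(x) must equal length(y).")
  p <- ncol(x)
  fit <- switch(spec$family,
    MLR = {
      if (nrow(x) <= p) stop_input("MLR needs n > number of predictors.")
      if (qr(cbind(1, x))$rank < p + 1) {
        stop_input("singular design matrix for MLR.")
      }
      df <- data.frame(y = y, x)
      stats::lm(y ~ ., data = df)
    },
    PLSR = {
      if (spec$ncomp > min(p, qr(scale(x, scale = FALSE))$rank)) {
        stop_input("PLSR `ncomp` exceeds the predictor rank.")
      }
      mixOmics::pls(x, y, ncomp = spec$ncomp, mode = "regression", scale = TRUE)
    },
    SVR = {
      ctr <- colMeans(x)
      scl <- apply(x, 2, stats::sd)
      scl[scl == 0] <- 1
      xs <- scale(x, ctr, scl)
      gamma <- spec$gamma
      if (is.null(gamma)) {
        v <- mean(apply(xs, 2, stats::var))
        gamma <- 1 / (p * max(v, 1e-12))
      }
      list(
        svm = e1071::svm(
          x = xs, y = y, type = "eps-regression", kernel = "radial",
          cost = spec$cost, epsilon = spec$epsilon, gamma = gamma,
          scale = FALSE
        ),
        centre = ctr, scale = scl
      )
    },
    RFR = {
      df <- data.frame(y = y, x)
      ranger::ranger(
        y ~ ., data = df,
        num.trees = spec$num_trees,
        mtry = p,
        min.node.size = spec$min_split,
        min.bucket = spec$min_leaf,
        max.depth = spec$max_depth,
        replace = TRUE,
        seed = spec$seed
      )
    }
  )
  structure(
    list(spec = spec, fit = fit, predictors = colnames(x)),
    class = "canopyn_model"
  )
}

#' @rdname fit_model
#' @param model A fitted `canopyn_model`.
#' @param newdata Predictor matrix or data frame.
#' @return `predict_model()`: numeric predictions.
#' @export
predict_model <- function(model, newdata) {
  if (!inherits(model, "canopyn_model")) stop_input("not a canopyn_model.")
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  if (!is.null(model$predictors)) colnames(x) <- model$predictors
  switch(model$spec$family,
    MLR = as.numeric(stats::predict(model$fit, newdata = as.data.frame(x))),
    PLSR = {
      pr <- stats::predict(model$fit, newdata = x)$predict
      as.numeric(pr[, 1, model$spec$ncomp])
    },
    SVR = {
      xs <- scale(x, model$fit$centre, model$fit$scale)
      as.numeric(stats::predict(model$fit$svm, xs))
    },
    RFR = as.numeric(stats::predict(model$fit, data = as.data.frame(x))$predictions)
  )
}

#' Regression accuracy metrics
#'
#' `rmse = sqrt(mean((yhat - y)^2))` and `mre = mean(|y - yhat| / y)`.
#' R2 is reported in two variants: `r2` is the out-of-sample definition
#' `1 - SS_res / SS_tot` (primary; can be negative for predictions worse than
#' the mean), and `r2_ratio` is the variance-ratio form
#' `sum((yhat - ybar)^2) / sum((y - ybar)^2)`, which equals `r2` only for
#' in-sample ordinary least squares.
#'
#' @param y Observed values.
#' @param y_hat Predicted values.
#' @param mre Compute the mean relative error? Requires all `y != 0`.
#'
#' @return A one-row tibble: `r2`, `r2_ratio`, `rmse`, `mre`, `n`.
#' @export
#'
#' @examples
#' evaluate_predictions(c(1, 2, 3), c(1, 2, 4))
evaluate_predictions <- function(y, y_hat, mre = TRUE) {
  if (length(y) != length(y_hat)) stop_input("lengths differ.")
  if (any(!is.finite(y)) || any(!is.finite(y_hat))) stop_input("inputs must be finite.")
  n <- length(y)
  ybar <- mean(y)
  ss_tot <- sum((y - ybar)^2)
  ss_res <- sum((y - y_hat)^2)
  mre_val <- NA_real_
  if (mre) {
    if (any(y == 0)) stop_input("MRE undefined: some observed values are zero.")
    mre_val <- mean(abs(y - y_hat) / y)
  }
  tibble::tibble(
    r2 = 1 - ss_res / ss_tot,
    r2_ratio = sum((y_hat - ybar)^2) / ss_tot,
    rmse = sqrt(ss_res / n),
    mre = mre_val,
    n = n
  )
}

#' Leave-one-out cross-validation
#'
#' Each tree is predicted once by a model trained on the remaining n - 1
#' trees; the pooled held-out predictions are scored once (per-fold scores
#' are undefined with one sample). Stochastic families (RFR) are re-run
#' `repeats` times with seeds derived from the spec's seed; the metric spread
#' across repeats is reported as an SD, and the stored predictions come from
#' the first repeat.
#'
#' @param features A feature table from [assemble_features()], or any tibble
#'   with a `target` column, an id column `tree_id`, and numeric predictors.
#' @param spec A [model_spec()].
#' @param repeats Repeat count for stochastic families.
#'
#' @return An object of class `canopyn_cv`: list with `predictions`
#'   (tibble: tree_id, y, y_hat, fold), `metrics` (one-row tibble),
#'   `spread` (SD of metrics across repeats, stochastic only), `spec`,
#'   `failed_folds`. [tidy()] and [glance()] methods are available.
#' @export
loocv <- function(features, spec, repeats = 1) {
  if (!"target" %in% names(features)) stop_input("`features` needs a `target` column.")
  pred_cols <- setdiff(
    names(features)[vapply(features, is.numeric, logical(1))], "target"
  )
  if (length(pred_cols) == 0) stop_input("no numeric predictor columns.")
  x <- as.matrix(features[, pred_cols])
  y <- features$target
  n <- nrow(x)
  if (n < 5) stop_input("LOOCV needs n >= 5.")
  ids <- if ("tree_id" %in% names(features)) features$tree_id else as.character(seq_len(n))
  n_rep <- if (is_stochastic(spec)) max(1, repeats) else 1

  run_once <- function(rep_seed) {
    sp <- spec
    sp$seed <- rep_seed
    y_hat <- rep(NA_real_, n)
    failed <- integer(0)
    for (i in seq_len(n)) {
      res <- tryCatch(
        {
          m <- fit_model(sp, x[-i, , drop = FALSE], y[-i])
          predict_model(m, x[i, , drop = FALSE])
        },
        error = function(e) e
      )
      if (inherits(res, "error")) {
        failed <- c(failed, i)
      } else {
        y_hat[i] <- res
      }
    }
    list(y_hat = y_hat, failed = failed)
  }

  rep_seeds <- vapply(
    seq_len(n_rep),
    function(r) derive_seed(spec$seed, paste("loocv-rep", r)), numeric(1)
  )
  runs <- lapply(rep_seeds, run_once)
  ok <- !is.na(runs[[1]]$y_hat)
  if (!any(ok)) stop_input("every LOOCV fold failed.")
  mre_ok <- all(y[ok] != 0)
  metric_rows <- dplyr::bind_rows(lapply(runs, function(r) {
    evaluate_predictions(y[ok], r$y_hat[ok], mre = mre_ok)
  }))
  spread <- if (n_rep > 1) {
    dplyr::summarise(metric_rows, dplyr::across(
      c("r2", "r2_ratio", "rmse", "mre"), stats::sd
    ))
  } else {
    NULL
  }
  structure(
    list(
      predictions = tibble::tibble(
        tree_id = ids, y = y, y_hat = runs[[1]]$y_hat,
        fold = seq_len(n)
      ),
      metrics = dplyr::summarise(metric_rows, dplyr::across(
        c("r2", "r2_ratio", "rmse", "mre"), mean
      ), n = dplyr::first(.data$n)),
      spread = spread,
      repeats = n_rep,
      spec = spec,
      failed_folds = runs[[1]]$failed,
      provenance = attr(features, "provenance")
    ),
    class = "canopyn_cv"
  )
}

#' @export
print.canopyn_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "LOOCV %s (n = %d): R2 = %.3f, RMSE = %.3f%s\n",
    x$spec$family, m$n, m$r2, m$rmse,
    if (length(x$failed_folds) > 0) {
      sprintf(" [%d failed fold(s)]", length(x$failed_folds))
    } else {
      ""
    }
  ))
  invisible(x)
}

#' Closed-form leave-one-out predictions for a linear model
#'
#' The leave-one-out identity for linear smoothers: with hat matrix `H`,
#' the held-out residual is `(y - yhat) / (1 - h_ii)`, so full refits are
#' unnecessary. Used as an independent oracle for the fold loop.
#'
#' @param x Predictor matrix.
#' @param y Response.
#' @return Numeric LOOCV predictions.
#' @export
loocv_linear_closed_form <- function(x, y) {
  x <- cbind(1, as.matrix(x))
  qx <- qr(x)
  if (qx$rank < ncol(x)) stop_input("singular design matrix.")
  h <- rowSums(qr.Q(qx)^2)
  fit <- qr.fitted(qx, y)
  y - (y - fit) / (1 - h)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing predictor `j`
#' on the remaining predictors. Exact collinearity yields `Inf` with a
#' warning naming the column.
#'
#' @param x Predictor matrix or data frame (`>= 2` columns, `n > p`).
#' @return A tibble with `predictor` and `vif`.
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  p <- ncol(x)
  if (p < 2) stop_input("VIF needs at least 2 predictors.")
  if (nrow(x) <= p) stop_input("VIF needs n > number of predictors.")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  out <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((x[, j] - mean(x[, j]))^2)
    if (ss_tot == 0) {
      return(1)
    }
    r2 <- 1 - ss_res / ss_tot
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  if (any(is.infinite(out))) {
    rlang::warn(sprintf(
      "exact collinearity: %s",
      paste(colnames(x)[is.infinite(out)], collapse = ", ")
    ))
  }
  tibble::tibble(predictor = colnames(x), vif = out)
}

#' Permutation feature importance
#'
#' Model-agnostic importance: the mean drop in out-of-permutation R2
#' (`1 - SS_res / SS_tot`) when one predictor column is shuffled. Shuffling
#' seeds derive from `seed`, so results are reproducible.
#'
#' @param model A fitted `canopyn_model`.
#' @param x Predictor matrix used for scoring.
#' @param y Observed response.
#' @param n_repeats Shuffles per predictor.
#' @param seed Integer seed.
#'
#' @return A tibble with `predictor` and `importance` (mean R2 drop).
#' @export
permutation_importance <- function(model, x, y, n_repeats = 10, seed = 1) {
  if (!inherits(model, "canopyn_model")) stop_input("not a canopyn_model.")
  assert_scalar_number(n_repeats, "n_repeats", lower = 1)
  x <- as.matrix(x)
  base <- evaluate_predictions(y, predict_model(model, x), mre = FALSE)$r2
  p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  imp <- vapply(seq_len(p), function(j) {
    drops <- vapply(seq_len(n_repeats), function(r) {
      xp <- x
      perm <- with_seed(
        derive_seed(seed, paste("perm", j, r)),
        sample.int(nrow(x))
      )
      xp[, j] <- xp[perm, j]
      base - evaluate_predictions(y, predict_model(model, xp), mre = FALSE)$r2
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  tibble::tibble(predictor = colnames(x), importance = imp)
}
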