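linear_features <- function(n = 16, noise = 0, seed = 2) {
  set.seed(seed)
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, c("ndsi", "ph", "cd", "cv")))
  y <- as.numeric(x %*% c(2, 1, -1, 0.5)) + 3 + rnorm(n, 0, noise)
  feats <- tibble::as_tibble(x)
  feats$target <- y
  feats$tree_id <- as.character(seq_len(n))
  list(features = feats, x = x, y = y)
}

test_that("feature assembly joins sources per tree and flags mismatches", {
  bundle <- generate_dataset(
    experiment_design(sites = "Lishi", stages = "FES", trees_per_cell = 1),
    scenes = default_scenes(100), seed = 6,
    cloud_args = list(point_density = 150, ground_density = 5)
  )
  gt <- bundle$ground_truth # 12 trees
  met <- extract_tree_metrics(bundle$clouds)
  sel <- tibble::tibble(lambda_i = 560, lambda_j = 690)
  feats <- assemble_features(gt, bundle$spectra, met, sel,
    trait = "cnc", hsi_altitude = 100, lidar_altitude = 60
  )
  expect_equal(dim(feats), c(nrow(gt), 6))
  expect_named(feats, c("tree_id", "ndsi", "ph", "cd", "cv", "target"))
  expect_equal(feats$target, gt$cnc)
  prov <- attr(feats, "provenance")
  expect_equal(prov$hsi_altitude, 100)
  expect_equal(prov$lidar_altitude, 60)

  # uniform-altitude configuration is just both arguments equal
  feats2 <- assemble_features(gt, bundle$spectra[["100"]], met, sel,
    trait = "agna", hsi_altitude = 100, lidar_altitude = 100
  )
  expect_equal(attr(feats2, "provenance")$lidar_altitude, 100)

  expect_error(
    assemble_features(gt, bundle$spectra, met[-1, ], sel, trait = "cnc", hsi_altitude = 100),
    met$tree_id[1]
  )
  expect_error(
    assemble_features(gt, bundle$spectra, met, sel, trait = "cnc", hsi_altitude = 80),
    "altitude"
  )
})

test_that("model families fit, predict and respect their contracts", {
  lf <- linear_features(20, noise = 0)
  # MLR recovers an exact linear relationship
  m <- fit_model(model_spec("MLR"), lf$x, lf$y)
  expect_equal(unname(coef(m$fit)[-1]), c(2, 1, -1, 0.5), tolerance = 1e-8)
  expect_equal(predict_model(m, lf$x), lf$y, tolerance = 1e-8)

  # PLSR with full-rank components equals OLS
  pls_full <- fit_model(model_spec("PLSR", ncomp = 4), lf$x, lf$y)
  expect_equal(predict_model(pls_full, lf$x), predict_model(m, lf$x), tolerance = 1e-6)

  # stochastic family: identical under one seed, different under another
  lfn <- linear_features(24, noise = 0.5, seed = 3)
  r1 <- fit_model(model_spec("RFR", seed = 11), lfn$x, lfn$y)
  r2 <- fit_model(model_spec("RFR", seed = 11), lfn$x, lfn$y)
  r3 <- fit_model(model_spec("RFR", seed = 12), lfn$x, lfn$y)
  expect_identical(predict_model(r1, lfn$x), predict_model(r2, lfn$x))
  expect_false(identical(predict_model(r1, lfn$x), predict_model(r3, lfn$x)))

  s <- fit_model(model_spec("SVR"), lfn$x, lfn$y)
  expect_gt(cor(predict_model(s, lfn$x), lfn$y), 0.8)

  sing <- cbind(lf$x, dup = lf$x[, 1])
  expect_error(fit_model(model_spec("MLR"), sing, lf$y), "singular")
  expect_error(fit_model(model_spec("PLSR", ncomp = 9), lf$x, lf$y), "ncomp")
})

test_that("LOOCV matches the closed-form linear identity and pools correctly", {
  lfn <- linear_features(18, noise = 0.4, seed = 5)
  cv <- loocv(lfn$features, model_spec("MLR"))
  expect_equal(
    cv$predictions$y_hat,
    loocv_linear_closed_form(lfn$x, lfn$y),
    tolerance = 1e-8
  )
  # stored metrics reproduce from stored predictions exactly
  re <- evaluate_predictions(cv$predictions$y, cv$predictions$y_hat, mre = FALSE)
  expect_equal(re$r2, cv$metrics$r2, tolerance = 1e-12)
  expect_equal(re$rmse, cv$metrics$rmse, tolerance = 1e-12)
  expect_equal(nrow(cv$predictions), 18) # exactly one held-out prediction each

  # noiseless linear target: interpolation
  lf0 <- linear_features(16, noise = 0)
  cv0 <- loocv(lf0$features, model_spec("MLR"))
  expect_equal(cv0$metrics$r2, 1, tolerance = 1e-8)
  expect_lt(cv0$metrics$rmse, 1e-8)

  # pure-noise target: pooled R2 near zero or negative in most draws
  low <- vapply(1:20, function(s) {
    lfr <- linear_features(16, seed = 300 + s)
    lfr$features$target <- rnorm(16)
    loocv(lfr$features, model_spec("MLR"))$metrics$r2 < 0.3
  }, logical(1))
  expect_gte(mean(low), 0.9)

  # stochastic repeats: spread reported, predictions from first repeat
  cvr <- loocv(lfn$features, model_spec("RFR", seed = 2), repeats = 3)
  expect_equal(cvr$repeats, 3)
  expect_true(is.finite(cvr$spread$r2))
  expect_error(loocv(lfn$features[1:4, ], model_spec("MLR")), "n >= 5")
})

test_that("accuracy metrics match hand-computed values", {
  ev <- evaluate_predictions(c(1, 2, 3), c(1, 2, 4))
  expect_equal(ev$rmse, sqrt(1 / 3))
  expect_equal(ev$mre, 1 / 9)
  perfect <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$r2_ratio, 1)
  expect_equal(c(perfect$rmse, perfect$mre), c(0, 0))
  mean_pred <- evaluate_predictions(c(1, 2, 3), rep(2, 3))
  expect_equal(mean_pred$r2, 0)
  expect_equal(mean_pred$r2_ratio, 0)
  expect_error(evaluate_predictions(c(0, 1, 2), c(1, 1, 1)), "zero")
  expect_silent(evaluate_predictions(c(0, 1, 2), c(1, 1, 1), mre = FALSE))
})

test_that("VIF matches its closed form and flags exact collinearity", {
  set.seed(8)
  x_orth <- qr.Q(qr(matrix(rnorm(200 * 3), 200, 3)))
  colnames(x_orth) <- c("a", "b", "c")
  v <- vif(x_orth)
  expect_equal(v$vif, rep(1, 3), tolerance = 0.05)

  # two predictors with correlation r: VIF = 1 / (1 - r^2)
  set.seed(9)
  x1 <- rnorm(5000)
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(5000)
  v2 <- vif(cbind(x1 = x1, x2 = x2))
  expect_equal(v2$vif, rep(1 / (1 - 0.81), 2), tolerance = 0.15)

  expect_warning(v3 <- vif(cbind(a = x1, b = x1, c = x2)), "collinearity")
  expect_true(all(is.infinite(v3$vif[1:2])))
  expect_error(vif(matrix(1:10, ncol = 1)), "2 predictors")
})

test_that("permutation importance isolates the informative predictor", {
  set.seed(10)
  x <- cbind(x1 = rnorm(60), x2 = rnorm(60), flat = rep(1, 60))
  y <- 3 * x[, 1] + rnorm(60, 0, 0.1)
  m <- fit_model(model_spec("RFR", seed = 4), x, y)
  imp <- permutation_importance(m, x, y, n_repeats = 5, seed = 1)
  expect_gt(imp$importance[imp$predictor == "x1"], 0.5)
  expect_lt(abs(imp$importance[imp$predictor == "x2"]), 0.1)
  expect_equal(imp$importance[imp$predictor == "flat"], 0)
  imp2 <- permutation_importance(m, x, y, n_repeats = 5, seed = 1)
  expect_identical(imp, imp2)
})
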