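#' Fit a bagged regression-tree ensemble for WOI hour offsets
#'
#' Grows `n_trees` regression trees on bootstrap resamples of the training
#' data (n draws with replacement per tree). At each node, `mtry` candidate
#' features are sampled without replacement and the best axis-aligned split
#' by sum-of-squares reduction is taken; leaves store the mean response of
#' their in-bag observations. Split ties resolve deterministically to the
#' lowest feature index, then the lowest threshold. The per-sample
#' bootstrap membership counts `N[i, b]` are recorded so that out-of-bag
#' predictions ([oob_predictions()]) and infinitesimal-jackknife standard
#' errors ([ij_variance()]) can be computed afterwards.
#'
#' @param X Numeric feature matrix, samples in rows (typically marker genes
#'   in columns, log-scale).
#' @param y Numeric response: signed hour-offset labels.
#' @param n_trees Number of trees (default 1000).
#' @param mtry Features tried per split; default `ceiling(p / 3)`, the
#'   usual regression-forest choice.
#' @param min_node_size Nodes of this size or smaller are not split
#'   (default 5).
#' @param max_depth Optional depth bound; 0 (default) means unlimited.
#' @param seed Integer seed; the fit is fully reproducible from it.
#' @return An object of class `woi_forest`: list with `trees`, `N`
#'   (n x B bootstrap counts), `X_train`, `y_train`, and the
#'   hyperparameters.
#' @export
woi_forest <- function(X, y, n_trees = 1000L,
                       mtry = ceiling(ncol(X) / 3),
                       min_node_size = 5L, max_depth = 0L, seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported", call. = FALSE)
  if (!all(is.finite(y))) stop("y must be finite", call. = FALSE)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (nrow(X) < 2L) stop("need at least 2 training samples", call. = FALSE)
  n_trees <- as.integer(n_trees)
  mtry <- as.integer(mtry)
  if (n_trees < 1L) stop("n_trees must be >= 1", call. = FALSE)
  if (mtry < 1L || mtry > ncol(X)) {
    stop("mtry must lie in [1, ncol(X)]", call. = FALSE)
  }
  if (min_node_size < 1L) stop("min_node_size must be >= 1", call. = FALSE)

  fit <- .grow_forest_cpp(X, y, n_trees, mtry, as.integer(min_node_size),
                          as.integer(max_depth), as.numeric(seed))
  model <- structure(
    list(trees = fit$trees, N = fit$N,
         X_train = X, y_train = y,
         n_trees = n_trees, mtry = mtry,
         min_node_size = as.integer(min_node_size),
         max_depth = as.integer(max_depth), seed = as.integer(seed),
         feature_names = colnames(X)),
    class = "woi_forest")
  if (stats::var(y) > 0 && all_root_leaves(model)) {
    warning("all trees are root leaves (constant features?); ",
            "predictions collapse to bootstrap means", call. = FALSE)
  }
  model
}

all_root_leaves <- function(model) {
  all(vapply(model$trees, function(tr) tr$feature[1] < 0, logical(1)))
}

#' @export
print.woi_forest <- function(x, ...) {
  p <- if (!is.null(x$X_train)) ncol(x$X_train) else x$n_features
  cat("WOI hour-offset forest:", x$n_trees, "trees,",
      p, "features, n =", nrow(x$N), "\n")
  cat("  mtry =", x$mtry, ", min_node_size =", x$min_node_size,
      ", seed =", x$seed, "\n")
  invisible(x)
}

check_newdata <- function(model, newdata) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  n_feat <- if (!is.null(model$X_train)) ncol(model$X_train) else model$n_features
  if (ncol(newdata) != n_feat) {
    stop("newdata has ", ncol(newdata), " features; model was trained on ",
         n_feat, call. = FALSE)
  }
  newdata
}

# per-tree predictions t_b(x): rows = observations, cols = trees
per_tree_predictions <- function(model, newdata) {
  .predict_forest_cpp(model$trees, check_newdata(model, newdata))
}

#' Predict hour offsets with standard errors
#'
#' The ensemble prediction is the mean of the per-tree leaf values; its
#' sampling uncertainty is estimated by the infinitesimal jackknife
#' ([ij_variance()]) unless `se_method = "none"`.
#'
#' @param object A [woi_forest()].
#' @param newdata Feature matrix (or vector for a single observation).
#' @param se_method `"ij"` (infinitesimal jackknife with finite-B bias
#'   correction, default), `"jackknife_oob"` (jackknife-after-bootstrap
#'   built from out-of-bag tree means), or `"none"`.
#' @param calibrate Empirical-Bayes calibration of the variance estimates
#'   across the prediction batch; see [ij_variance()]. Default `NULL`
#'   (automatic).
#' @param ... Unused.
#' @return Data frame with `offset_hours` and (unless `"none"`) `se_hours`.
#' @export
predict.woi_forest <- function(object, newdata,
                               se_method = c("ij", "jackknife_oob", "none"),
                               calibrate = NULL, ...) {
  se_method <- match.arg(se_method)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  t_mat <- per_tree_predictions(object, newdata)
  out <- data.frame(offset_hours = rowMeans(t_mat))
  if (se_method != "none") {
    out$se_hours <- sqrt(ij_variance(object, newdata, method = se_method,
                                     calibrate = calibrate, .t_mat = t_mat))
  }
  out
}

#' Infinitesimal-jackknife variance of forest predictions
#'
#' For a test point x with per-tree predictions `t_b(x)` and bootstrap
#' membership counts `N[i, b]`, the raw infinitesimal-jackknife variance is
#' `V = sum_i Cov_b(N[i, b], t_b(x))^2`; Monte-Carlo noise from the finite
#' number of trees is removed with the bias correction
#' `V - (n / B^2) * sum_b (t_b - tbar)^2`, and the result is floored at 0.
#' The `"jackknife_oob"` method instead uses the jackknife-after-bootstrap
#' estimator `((n - 1) / n) * sum_i (tbar_oob(i) - tbar)^2` built from
#' out-of-bag tree means, with the matching `(e - 1) n / B^2` correction.
#'
#' Individual bias-corrected estimates are themselves noisy (and
#' right-skewed) when `B` is not large relative to `n`. When variances are
#' requested for a batch of test points, an empirical-Bayes calibration
#' stabilizes them: the Monte-Carlo noise variance of the estimates is
#' measured by recomputing them on half of the trees, and the raw values
#' are shrunk toward their cross-point mean by the usual normal-normal
#' posterior factor `tau^2 / (tau^2 + sigma^2)`. This follows the
#' calibration shipped with the reference infinitesimal-jackknife
#' implementations for bagged ensembles. By default calibration switches
#' on automatically for batches of more than 20 test points and off for
#' smaller batches (where the cross-point moments cannot be estimated).
#'
#' @param model A [woi_forest()] (must retain membership counts; `B >= 2`).
#' @param newdata Feature matrix or single-observation vector.
#' @param method `"ij"` (default) or `"jackknife_oob"`.
#' @param correct Apply the finite-B bias correction (default `TRUE`).
#' @param calibrate `TRUE`, `FALSE`, or `NULL` (default: calibrate batches
#'   of more than 20 points). Only applies to `method = "ij"`.
#' @param .t_mat Internal: precomputed per-tree predictions.
#' @return Numeric vector of variance estimates (hours squared), one per
#'   row of `newdata`.
#' @export
ij_variance <- function(model, newdata, method = c("ij", "jackknife_oob"),
                        correct = TRUE, calibrate = NULL, .t_mat = NULL) {
  stopifnot(inherits(model, "woi_forest"))
  method <- match.arg(method)
  B <- model$n_trees
  if (B < 2L) stop("variance undefined for fewer than 2 trees", call. = FALSE)
  if (is.null(.t_mat)) {
    if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
    .t_mat <- per_tree_predictions(model, newdata)
  }
  n <- nrow(model$N)
  tc <- .t_mat - rowMeans(.t_mat)            # center per test point
  boot_var <- rowSums(tc^2)                  # sum_b (t_b - tbar)^2
  if (method == "ij") {
    raw_ij <- function(tm, N) {
      Bs <- ncol(tm)
      tcs <- tm - rowMeans(tm)
      v <- rowSums((tcrossprod(tcs, N) / Bs)^2)
      if (correct) v <- v - (n / Bs^2) * rowSums(tcs^2)
      v
    }
    v <- raw_ij(.t_mat, model$N)
    npts <- nrow(.t_mat)
    if (is.null(calibrate)) calibrate <- npts > 20
    if (isTRUE(calibrate)) {
      if (npts <= 2) {
        warning("too few test points to calibrate; returning raw estimates",
                call. = FALSE)
      } else {
        # noise level of the raw estimates, from a deterministic half-forest
        half <- seq_len(B) %% 2L == 0L
        v_half <- pmax(raw_ij(.t_mat[, half, drop = FALSE],
                              model$N[, half, drop = FALSE]), 0)
        sigma2 <- mean((v_half - pmax(v, 0))^2)
        tau2 <- max(stats::var(pmax(v, 0)) - sigma2, 0)
        shrink <- if (tau2 + sigma2 > 0) tau2 / (tau2 + sigma2) else 1
        v <- mean(pmax(v, 0)) + shrink * (pmax(v, 0) - mean(pmax(v, 0)))
      }
    }
  } else {
    M <- (model$N == 0L) + 0                 # OOB indicator, n x B
    n_oob <- rowSums(M)
    if (any(n_oob == 0)) {
      warning(sum(n_oob == 0), " training sample(s) in-bag in every tree; ",
              "dropped from the jackknife", call. = FALSE)
    }
    keep <- n_oob > 0
    tbar_oob <- tcrossprod(tc, M[keep, , drop = FALSE]) /
      rep(n_oob[keep], each = nrow(tc))      # ntest x n_keep, centered
    v <- ((n - 1) / n) * rowSums(tbar_oob^2)
    if (correct) v <- v - (exp(1) - 1) * (n / B^2) * boot_var
  }
  pmax(v, 0)
}

#' Out-of-bag predictions
#'
#' Sample i's out-of-bag prediction averages the predictions of the trees
#' whose bootstrap resample did not contain i. Samples that are in-bag in
#' every tree get `NA`.
#'
#' @param model A [woi_forest()].
#' @param X_train The training matrix; defaults to the copy stored in the
#'   model (a deserialized model does not carry one).
#' @return Numeric vector of OOB offset predictions, one per training
#'   sample.
#' @export
oob_predictions <- function(model, X_train = model$X_train) {
  stopifnot(inherits(model, "woi_forest"))
  if (is.null(X_train)) {
    stop("model carries no training matrix; pass X_train", call. = FALSE)
  }
  t_mat <- per_tree_predictions(model, X_train)   # n x B
  oob <- model$N == 0L
  n_oob <- rowSums(oob)
  out <- rowSums(t_mat * oob) / n_oob
  out[n_oob == 0] <- NA_real_
  out
}

#' Patient-grouped k-fold cross-validation over a hyperparameter grid
#'
#' Folds partition *patients*, not samples, so a patient contributing
#' several biopsies (three-point training data) never appears in both the
#' training and held-out side of a fold. For each hyperparameter setting,
#' held-out R-squared (`1 - SS_res / SS_tot`) and RMSE are computed per
#' fold; the setting with the highest mean R-squared is selected.
#'
#' @param X Feature matrix, samples in rows.
#' @param y Hour-offset labels.
#' @param patient_ids Patient id per sample (defines the fold grouping).
#' @param k Number of folds (default 10); `k` equal to the number of
#'   patients gives leave-one-patient-out.
#' @param hp_grid Data frame of hyperparameter settings with any of the
#'   columns `n_trees`, `mtry`, `min_node_size`, `max_depth`; one row per
#'   setting. Defaults to a single row of [woi_forest()] defaults.
#' @param seed Integer seed (fold assignment and tree growing).
#' @return An object of class `cv_report`: list with `fold_assignments`
#'   (patient -> fold), `folds` (per-setting, per-fold R-squared and RMSE),
#'   `summary` (mean R-squared per setting), and `selected` (best setting,
#'   as a one-row data frame).
#' @export
cv_forest <- function(X, y, patient_ids, k = 10L, hp_grid = NULL, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), length(patient_ids) == length(y))
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  patients <- unique(patient_ids)
  if (k > length(patients)) {
    stop("more folds than patients", call. = FALSE)
  }
  if (is.null(hp_grid)) {
    hp_grid <- data.frame(n_trees = 500L, mtry = ceiling(ncol(X) / 3),
                          min_node_size = 5L, max_depth = 0L)
  }
  defaults <- list(n_trees = 500L, mtry = ceiling(ncol(X) / 3),
                   min_node_size = 5L, max_depth = 0L)
  for (nm in names(defaults)) {
    if (is.null(hp_grid[[nm]])) hp_grid[[nm]] <- defaults[[nm]]
  }

  fold_of <- withr::with_seed(as.integer(seed), {
    stats::setNames(sample(rep_len(seq_len(k), length(patients))), patients)
  })
  sample_fold <- fold_of[as.character(patient_ids)]

  rows <- list()
  for (s in seq_len(nrow(hp_grid))) {
    for (fold in seq_len(k)) {
      test <- sample_fold == fold
      fit <- woi_forest(X[!test, , drop = FALSE], y[!test],
                        n_trees = hp_grid$n_trees[s],
                        mtry = hp_grid$mtry[s],
                        min_node_size = hp_grid$min_node_size[s],
                        max_depth = hp_grid$max_depth[s],
                        seed = as.integer(seed) + 1000L * fold + s)
      pred <- predict(fit, X[test, , drop = FALSE], se_method = "none")
      ss_tot <- sum((y[test] - mean(y[test]))^2)
      ss_res <- sum((y[test] - pred$offset_hours)^2)
      r2 <- if (ss_tot <= 0) {
        warning("fold ", fold, " has constant held-out truth; R^2 undefined",
                call. = FALSE)
        NA_real_
      } else 1 - ss_res / ss_tot
      rows[[length(rows) + 1L]] <- data.frame(
        setting = s, fold = fold, r_squared = r2,
        rmse = sqrt(ss_res / sum(test)))
    }
  }
  folds <- do.call(rbind, rows)
  mean_r2 <- tapply(folds$r_squared, folds$setting, mean, na.rm = TRUE)
  best <- as.integer(names(which.max(mean_r2)))
  structure(list(fold_assignments = fold_of, folds = folds,
                 summary = data.frame(setting = as.integer(names(mean_r2)),
                                      mean_r_squared = as.numeric(mean_r2)),
                 selected = hp_grid[best, , drop = FALSE],
                 k = k, seed = as.integer(seed)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Patient-grouped", x$k, "-fold cross-validation\n")
  cat("  mean R^2 by setting:",
      paste(sprintf("%.3f", x$summary$mean_r_squared), collapse = ", "), "\n")
  cat("  selected: n_trees =", x$selected$n_trees, ", mtry =",
      x$selected$mtry, ", min_node_size =", x$selected$min_node_size, "\n")
  invisible(x)
}

#' Serialize a forest to a single JSON document
#'
#' Writes trees, bootstrap membership counts, hyperparameters and seed as
#' plain JSON (the training matrix is not stored; pass it explicitly to
#' [oob_predictions()] after reading).
#'
#' @param model A [woi_forest()].
#' @param path Output path.
#' @return `write_forest_json` returns `path` invisibly; `read_forest_json`
#'   a `woi_forest` that predicts identically to the original.
#' @export
write_forest_json <- function(model, path) {
  stopifnot(inherits(model, "woi_forest"))
  doc <- list(
    format = "woi_forest-1",
    n_trees = model$n_trees, mtry = model$mtry,
    min_node_size = model$min_node_size, max_depth = model$max_depth,
    seed = model$seed, n_features = ncol(model$X_train),
    feature_names = model$feature_names,
    y_train = model$y_train,
    N = as.vector(model$N), n_train = nrow(model$N),
    trees = lapply(model$trees, function(tr) {
      lapply(tr, as.vector)
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_forest_json
#' @export
read_forest_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  stopifnot(identical(doc$format, "woi_forest-1"))
  trees <- lapply(doc$trees, function(tr) {
    list(feature = as.integer(tr$feature),
         threshold = as.numeric(tr$threshold),
         left = as.integer(tr$left),
         right = as.integer(tr$right),
         value = as.numeric(tr$value))
  })
  structure(
    list(trees = trees,
         N = matrix(as.integer(doc$N), nrow = doc$n_train),
         X_train = NULL, y_train = as.numeric(doc$y_train),
         n_trees = as.integer(doc$n_trees), mtry = as.integer(doc$mtry),
         min_node_size = as.integer(doc$min_node_size),
         max_depth = as.integer(doc$max_depth),
         seed = as.integer(doc$seed),
         feature_names = doc$feature_names,
         n_features = as.integer(doc$n_features)),
    class = "woi_forest")
}
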