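test_that("fits are bit-identical under a fixed seed", {
  fx <- smooth_fixture()
  m1 <- woi_forest(fx$X, fx$y, n_trees = 50, seed = 3)
  m2 <- woi_forest(fx$X, fx$y, n_trees = 50, seed = 3)
  expect_identical(m1$trees, m2$trees)
  expect_identical(m1$N, m2$N)
  xnew <- matrix(seq(-2, 2, length.out = 9), ncol = 1)
  expect_identical(predict(m1, xnew), predict(m2, xnew))
  m3 <- woi_forest(fx$X, fx$y, n_trees = 50, seed = 4)
  expect_false(identical(m1$trees, m3$trees))
})

test_that("bootstrap membership counts sum to n in every tree", {
  fx <- smooth_fixture(n = 60)
  m <- woi_forest(fx$X, fx$y, n_trees = 40, seed = 1)
  expect_true(all(colSums(m$N) == 60))
})

test_that("a constant response is predicted exactly with zero SE", {
  X <- matrix(runif(80), 40, 2)
  m <- woi_forest(X, rep(7, 40), n_trees = 30, seed = 2)
  p <- predict(m, matrix(runif(10), 5, 2))
  expect_equal(p$offset_hours, rep(7, 5))
  expect_equal(p$se_hours, rep(0, 5))
})

test_that("a single stump tree predicts its bootstrap-sample mean", {
  withr::with_seed(5, {
    X <- matrix(rnorm(30), 30, 1)
    y <- rnorm(30)
  })
  m <- suppressWarnings(
    woi_forest(X, y, n_trees = 1, min_node_size = 30, seed = 9))
  # oracle: the bootstrap-sample mean reconstructed from the recorded counts
  boot_mean <- sum(m$N[, 1] * y) / 30
  p <- predict(m, matrix(0), se_method = "none")
  expect_equal(p$offset_hours, boot_mean, tolerance = 1e-12)
})

test_that("a pure binary split is recovered to within an hour", {
  withr::with_seed(6, {
    x <- rep(c(0, 1), each = 20)
    y <- 100 * x + rnorm(40, sd = 0.01)
  })
  m <- woi_forest(matrix(x, ncol = 1), y, n_trees = 300,
                  min_node_size = 1, seed = 2)
  p <- predict(m, matrix(c(0, 1), ncol = 1), se_method = "none")
  expect_lt(abs(p$offset_hours[1] - 0), 1)
  expect_lt(abs(p$offset_hours[2] - 100), 1)
})

test_that("predictions stay within the training-response range", {
  fx <- smooth_fixture(n = 80)
  m <- woi_forest(fx$X, fx$y, n_trees = 60, seed = 8)
  p <- predict(m, matrix(seq(-10, 10, length.out = 41), ncol = 1),
               se_method = "none")
  expect_true(all(p$offset_hours >= min(fx$y)))
  expect_true(all(p$offset_hours <= max(fx$y)))
})

test_that("constant features degrade to root leaves with a warning", {
  X <- matrix(1, 30, 3)
  y <- rnorm(30)
  expect_warning(m <- woi_forest(X, y, n_trees = 10, seed = 1),
                 "root leaves")
  p <- predict(m, matrix(1, 1, 3), se_method = "none")
  expect_true(is.finite(p$offset_hours))
})

test_that("hyperparameter and input validation errors are raised", {
  fx <- smooth_fixture(n = 20)
  expect_error(woi_forest(fx$X, fx$y, mtry = 2), "mtry")
  expect_error(woi_forest(fx$X, fx$y[-1], n_trees = 5), "nrow")
  expect_error(woi_forest(fx$X, c(fx$y[-1], NA), n_trees = 5), "missing|finite")
  m <- woi_forest(fx$X, fx$y, n_trees = 5, seed = 1)
  expect_error(predict(m, matrix(0, 1, 3)), "features")
  m1 <- woi_forest(fx$X, fx$y, n_trees = 1, seed = 1)
  expect_error(ij_variance(m1, matrix(0)), "2 trees")
})

test_that("IJ variance matches a direct covariance-formula oracle", {
  withr::with_seed(12, {
    X <- matrix(rnorm(10), 5, 2)
    y <- rnorm(5)
  })
  m <- woi_forest(X, y, n_trees = 10, min_node_size = 1, seed = 3)
  xnew <- matrix(c(0.2, -0.4), 1, 2)
  t_vec <- drop(receptivr:::per_tree_predictions(m, xnew))
  expect_equal(ij_variance(m, xnew), ij_oracle(m$N, t_vec),
               tolerance = 1e-10)
  expect_equal(ij_variance(m, xnew, correct = FALSE),
               ij_oracle(m$N, t_vec, correct = FALSE), tolerance = 1e-10)
  # larger model, several test points
  fx <- smooth_fixture(n = 40)
  m2 <- woi_forest(fx$X, fx$y, n_trees = 25, seed = 5)
  xs <- matrix(c(-1, 0, 1), ncol = 1)
  v <- ij_variance(m2, xs)
  for (i in 1:3) {
    t_vec <- drop(receptivr:::per_tree_predictions(m2, xs[i, , drop = FALSE]))
    expect_equal(v[i], ij_oracle(m2$N, t_vec), tolerance = 1e-10)
  }
})

test_that("OOB sets have the expected ~e^-1 occupancy and define predictions", {
  fx <- smooth_fixture(n = 50)
  m <- woi_forest(fx$X, fx$y, n_trees = 600, seed = 7)
  oob_frac <- mean(m$N == 0)
  expect_lt(abs(oob_frac - exp(-1)), 0.05)
  oob <- oob_predictions(m)
  expect_true(all(is.finite(oob)))  # at B=600 every sample lands OOB somewhere
  # OOB error should not beat resubstitution error
  inbag <- predict(m, fx$X, se_method = "none")$offset_hours
  rmse_oob <- sqrt(mean((oob - fx$y)^2))
  rmse_in <- sqrt(mean((inbag - fx$y)^2))
  expect_gte(rmse_oob, rmse_in)
})

test_that("B=1 leaves only bootstrap-absent samples with OOB predictions", {
  fx <- smooth_fixture(n = 30)
  m <- woi_forest(fx$X, fx$y, n_trees = 1, seed = 11)
  oob <- oob_predictions(m)
  expect_identical(is.na(oob), m$N[, 1] > 0)
})

test_that("predictions agree closely with an independent forest implementation", {
  fx <- smooth_fixture(n = 150, noise_sd = 3, seed = 21)
  m <- woi_forest(fx$X, fx$y, n_trees = 400, seed = 2)
  xnew <- matrix(seq(-1.8, 1.8, length.out = 25), ncol = 1)
  mine <- predict(m, xnew, se_method = "none")$offset_hours
  rf <- ranger::ranger(y ~ x, data = data.frame(x = fx$X[, 1], y = fx$y),
                       num.trees = 400, min.node.size = 5, seed = 2)
  theirs <- predict(rf, data.frame(x = xnew[, 1]))$predictions
  expect_gt(cor(mine, theirs), 0.98)
  expect_lt(mean(abs(mine - theirs)), 3)
})

test_that("forests round-trip through JSON with identical predictions", {
  fx <- smooth_fixture(n = 40)
  m <- woi_forest(fx$X, fx$y, n_trees = 20, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_forest_json(m, path)
  m2 <- read_forest_json(path)
  xnew <- matrix(seq(-2, 2, length.out = 7), ncol = 1)
  expect_equal(predict(m2, xnew), predict(m, xnew), tolerance = 1e-12)
  expect_identical(m2$N, m$N)
  oob1 <- oob_predictions(m)
  oob2 <- oob_predictions(m2, X_train = fx$X)
  expect_equal(oob1, oob2, tolerance = 1e-12)
  expect_error(oob_predictions(m2), "training matrix")
})

test_that("patient-grouped folds partition patients", {
  withr::with_seed(14, {
    n_pat <- 12
    pid <- rep(sprintf("P%02d", 1:n_pat), each = 3)
    y <- rep(runif(n_pat, -48, 48), each = 3)
    X <- cbind(y + rnorm(length(y)), rnorm(length(y)))
  })
  cv <- suppressWarnings(
    cv_forest(X, y, pid, k = 4,
              hp_grid = data.frame(n_trees = 30), seed = 5))
  expect_equal(sort(names(cv$fold_assignments)), sort(unique(pid)))
  expect_true(all(table(cv$fold_assignments) == 3))
  # every sample of a patient is held out in the same fold
  expect_equal(length(cv$fold_assignments), n_pat)
  # leave-one-patient-out is the k = n_patients case
  cv_loo <- suppressWarnings(
    cv_forest(X, y, pid, k = n_pat,
              hp_grid = data.frame(n_trees = 10), seed = 5))
  expect_equal(length(unique(cv_loo$fold_assignments)), n_pat)
  expect_error(cv_forest(X, y, pid, k = 1), "k must be")
  expect_error(cv_forest(X, y, pid, k = 50), "more folds")
})

test_that("cross-validation separates signal from noise", {
  withr::with_seed(15, {
    n_pat <- 50
    y <- runif(n_pat, -96, 96)
    X <- cbind(y, matrix(rnorm(n_pat * 3), n_pat, 3))  # y leaks as a feature
  })
  pid <- sprintf("P%03d", seq_len(n_pat))
  cv_good <- cv_forest(X, y, pid, k = 5,
                       hp_grid = data.frame(n_trees = 200, mtry = 4,
                                            min_node_size = 1), seed = 6)
  expect_gt(max(cv_good$summary$mean_r_squared), 0.95)
  withr::with_seed(16, {
    y_noise <- rnorm(n_pat)
    X_noise <- matrix(rnorm(n_pat * 4), n_pat, 4)
  })
  cv_null <- cv_forest(X_noise, y_noise, pid, k = 5,
                       hp_grid = data.frame(n_trees = 100), seed = 7)
  expect_lt(max(cv_null$summary$mean_r_squared), 0.15)
})

test_that("cross-validation selects the better hyperparameter setting", {
  withr::with_seed(17, {
    n_pat <- 40
    y <- runif(n_pat, -96, 96)
    X <- cbind(y + rnorm(n_pat, sd = 4), matrix(rnorm(n_pat * 5), n_pat, 5))
  })
  pid <- sprintf("P%03d", seq_len(n_pat))
  grid <- data.frame(n_trees = c(150, 150), mtry = c(6, 6),
                     min_node_size = c(2, 40))  # second setting underfits
  cv <- suppressWarnings(cv_forest(X, y, pid, k = 5, hp_grid = grid, seed = 8))
  expect_equal(cv$selected$min_node_size, 2)
})
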