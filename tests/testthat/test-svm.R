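test_that("LOOCV is perfect on a separable toy and errors on bad input", {
  X <- rbind(c(1, 0), c(1, 0), c(-1, 0), c(-1, 0))
  colnames(X) <- c("A--B", "C--D")
  tb <- matrix_table(X, c(1L, 1L, -1L, -1L))
  rep <- loocv_classify(tb, svm_config())
  expect_equal(glance(rep)$accuracy, 1)
  expect_equal(nrow(rep$folds), 4)                      # one fold per subject
  expect_true(all(rep$folds$correct))
  expect_error(loocv_classify(tb[1:3, ], svm_config()), "at least 4")
  tb_one <- matrix_table(X, c(1L, 1L, 1L, -1L))
  expect_error(loocv_classify(tb_one, svm_config()), "at least 2 subjects")
})

test_that("accuracy equals the mean of per-fold correctness and counts add up", {
  cfg <- planted_config(41, n_patients = 12, n_controls = 14, R = 10,
                        n_discriminative = 4, n_clinical_linked = 2)
  ds <- generate_dataset(cfg)
  res <- run_boruta(ds$feature_table, quick_boruta(7, n_trees = 60, max_iter = 20))
  sel <- select_confirmed(ds$feature_table, res)
  rep <- loocv_classify(sel, svm_config())
  expect_equal(glance(rep)$accuracy, mean(rep$folds$correct))
  y <- rep$folds$observed
  pr <- rep$folds$predicted
  tp <- sum(pr == 1 & y == 1); fn <- sum(pr == -1 & y == 1)
  tn <- sum(pr == -1 & y == -1); fp <- sum(pr == 1 & y == -1)
  expect_equal(tp + fn, sum(y == 1))
  expect_equal(tn + fp, sum(y == -1))
})

test_that("confusion metrics reproduce hand counts and handle edge cases", {
  pred <- c(rep(1, 46), rep(-1, 2), rep(-1, 45), rep(1, 5))
  lab <- c(rep(1, 48), rep(-1, 50))
  m <- confusion_metrics(pred, lab)
  expect_equal(m$percent, c(92.9, 95.8, 90.0))
  all_ok <- confusion_metrics(lab, lab)
  expect_equal(all_ok$percent, c(100, 100, 100))
  none <- confusion_metrics(rep(-1, 98), lab)
  expect_equal(none$proportion[none$metric == "sensitivity"], 0)
  expect_error(confusion_metrics(numeric(0), numeric(0)), "empty")
  expect_error(confusion_metrics(1, c(1, -1)), "length")
})

test_that("linear-kernel weights recover the analytic max-margin solution", {
  X <- rbind(c(1, 0.5), c(1, -0.5), c(-1, 0.5), c(-1, -0.5))
  y <- factor(c(1, 1, -1, -1), levels = c(-1, 1))
  m <- e1071::svm(X, y, kernel = "linear", cost = 10, scale = FALSE,
                  tolerance = 1e-8)
  w <- extract_fold_weights(m)
  expect_equal(w[1], 1, tolerance = 1e-4)    # margin 2 along x1 -> w = (1, 0)
  expect_lt(abs(w[2]), 1e-6)
  expect_gt(w[1], 0)                         # oriented toward the +1 class
})

test_that("all-zero features get zero weight; duplicates split weight equally", {
  set.seed(12)
  n <- 30
  X <- cbind(rnorm(n) + rep(c(1.5, -1.5), each = n / 2), rnorm(n), 0)
  y <- factor(rep(c(1, -1), each = n / 2), levels = c(-1, 1))
  m <- e1071::svm(X, y, kernel = "linear", cost = 1, scale = FALSE)
  w <- extract_fold_weights(m)
  expect_equal(w[3], 0)
  # duplicated column: identical weights on the two copies
  Xd <- cbind(X[, 1], X[, 1], X[, 2])
  md <- e1071::svm(Xd, y, kernel = "linear", cost = 1, scale = FALSE,
                   tolerance = 1e-8)
  wd <- extract_fold_weights(md)
  expect_equal(wd[1], wd[2], tolerance = 1e-8)
  # symmetric hard-margin toy: duplicate halves sum to the original weight
  Xs <- rbind(c(1, 0.5), c(1, -0.5), c(-1, 0.5), c(-1, -0.5))
  ys <- factor(c(1, 1, -1, -1), levels = c(-1, 1))
  w0 <- extract_fold_weights(e1071::svm(Xs, ys, kernel = "linear", cost = 10,
                                        scale = FALSE, tolerance = 1e-8))
  Xsd <- cbind(Xs[, 1], Xs[, 1], Xs[, 2])
  wd2 <- extract_fold_weights(e1071::svm(Xsd, ys, kernel = "linear", cost = 10,
                                         scale = FALSE, tolerance = 1e-8))
  expect_equal(wd2[1] + wd2[2], w0[1], tolerance = 1e-4)
  expect_error(extract_fold_weights(lm(rnorm(4) ~ 1)), "svm")
})

test_that("linear weights agree with an independent dual-QP oracle", {
  skip_if_not_installed("kernlab")
  set.seed(33)
  for (trial in 1:3) {
    n <- 10
    X <- matrix(rnorm(n * 3), n, 3)
    yv <- rep(c(1, -1), each = n / 2)
    X[, 1] <- X[, 1] + 1.2 * yv
    C <- 1
    m <- e1071::svm(X, factor(yv, levels = c(-1, 1)), kernel = "linear",
                    cost = C, scale = FALSE, tolerance = 1e-10)
    w_impl <- extract_fold_weights(m)
    # dual C-SVC QP: min 1/2 a' (yy' * XX') a - 1'a, 0 <= a <= C, y'a = 0
    H <- (yv %o% yv) * tcrossprod(X)
    sol <- kernlab::ipop(c = matrix(-1, n, 1), H = H,
                         A = matrix(yv, 1, n), b = 0,
                         l = matrix(0, n, 1), u = matrix(C, n, 1),
                         r = 0, sigf = 12, maxiter = 200)
    a <- kernlab::primal(sol)
    w_oracle <- as.vector(t(X) %*% (a * yv))
    expect_equal(w_impl, w_oracle, tolerance = 1e-4)
  }
})

test_that("mean classification weights average folds elementwise", {
  expect_equal(mean_classification_weights(list(c(1, 0), c(0, 1))), c(0.5, 0.5))
  expect_equal(mean_classification_weights(list(c(2, 3), c(2, 3))), c(2, 3))
  expect_equal(mean_classification_weights(list(c(1, 0), c(0, 1))),
               mean_classification_weights(list(c(0, 1), c(1, 0))))
  expect_error(mean_classification_weights(list(c(1, 0), c(1, 0, 0))),
               "inconsistent")
})

test_that("permutation test hits the add-one floor and decreases with accuracy", {
  X <- rbind(matrix(rnorm(24, mean = 2), 6, 4), matrix(rnorm(24, mean = -2), 6, 4))
  tb <- matrix_table(X, rep(c(1L, -1L), each = 6))
  pt <- permutation_test(tb, svm_config(), n_perm = 19, seed = 4)
  expect_equal(pt$observed_accuracy, 1)
  expect_equal(pt$p_value, 1 / 20)            # observed beats every null
  expect_true(pt$p_value > 0 && pt$p_value <= 1)
  # p is decreasing in observed accuracy against a fixed null set
  p_lo <- (1 + sum(pt$null_accuracies >= 0.5)) / 20
  expect_gte(p_lo, pt$p_value)
  expect_error(permutation_test(tb, svm_config(), n_perm = 0), "at least 1")
})

test_that("nested selection inside each fold runs and labels its report", {
  cfg <- planted_config(51, n_patients = 8, n_controls = 8, R = 8,
                        n_discriminative = 5, effect_size = 2.5,
                        n_clinical_linked = 2)
  ds <- generate_dataset(cfg)
  bcfg <- quick_boruta(9, n_trees = 40, max_iter = 15)
  rep <- loocv_classify(ds$feature_table, svm_config(), selection = bcfg)
  expect_true(rep$nested_selection)
  expect_equal(nrow(rep$folds), 16)
  expect_equal(length(rep$mean_weights), ncol(ds$feature_table) - 2)
})
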