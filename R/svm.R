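# SVM classification of the selected connections under leave-one-out
# cross-validation, per-fold (pseudo-)primal weight extraction, confusion
# metrics, and the label-permutation significance test.

#' SVM configuration
#'
#' @param kernel `"rbf"` (default) or `"linear"`. With the linear kernel the
#'   extracted weights are the exact primal vector; with the RBF kernel the
#'   pseudo-primal surrogate `w = sum_i alpha_i y_i x_i` over support
#'   vectors is reported.
#' @param C soft-margin cost (default 1).
#' @param gamma RBF kernel width: a positive number, or `"scale"` (default)
#'   for `1 / (p * var(X))` computed on the (standardized) training fold.
#' @param standardize per-feature z-scoring using training-fold statistics,
#'   applied to the held-out subject (default TRUE).
#' @return an `svm_config` list.
#' @export
svm_config <- function(kernel = c("rbf", "linear"), C = 1, gamma = "scale",
                       standardize = TRUE) {
  kernel <- match.arg(kernel)
  stopifnot(C > 0)
  if (is.numeric(gamma)) stopifnot(gamma > 0)
  structure(list(kernel = kernel, C = C, gamma = gamma,
                 standardize = isTRUE(standardize)),
            class = "svm_config")
}

# Train-fold standardization statistics; zero-SD features are left unscaled.
fold_scaler <- function(Xtr) {
  mu <- colMeans(Xtr)
  s <- apply(Xtr, 2L, sd)
  s[s == 0] <- 1
  list(center = mu, scale = s)
}

apply_scaler <- function(X, sc) {
  sweep(sweep(X, 2L, sc$center, "-"), 2L, sc$scale, "/")
}

resolve_gamma <- function(cfg, X) {
  if (is.numeric(cfg$gamma)) return(cfg$gamma)
  v <- var(as.vector(X))
  if (!is.finite(v) || v == 0) return(1 / ncol(X))
  1 / (ncol(X) * v)
}

fit_svm <- function(Xtr, ytr, cfg) {
  check_binary_labels(ytr)
  sc <- if (cfg$standardize) fold_scaler(Xtr) else
    list(center = rep(0, ncol(Xtr)), scale = rep(1, ncol(Xtr)))
  Xs <- apply_scaler(Xtr, sc)
  gamma <- resolve_gamma(cfg, Xs)
  model <- e1071::svm(
    x = Xs, y = factor(ytr, levels = c(-1, 1)),
    kernel = if (cfg$kernel == "rbf") "radial" else "linear",
    cost = cfg$C, gamma = gamma, scale = FALSE
  )
  list(model = model, scaler = sc, gamma = gamma)
}

# e1071 orients decision values / dual coefficients toward whichever class
# it met first; flip so positive always means the +1 (patient) class.
svm_sign <- function(model) {
  if (model$labels[1L] == which(model$levels == "1")) 1 else -1
}

predict_svm <- function(fit, Xnew) {
  Xs <- apply_scaler(Xnew, fit$scaler)
  pr <- stats::predict(fit$model, Xs, decision.values = TRUE)
  dv <- as.numeric(attr(pr, "decision.values")) * svm_sign(fit$model)
  list(label = as.integer(as.character(pr)), decision_value = dv)
}

#' Extract the (pseudo-)primal weight vector of a fitted SVM
#'
#' Computes `w = sum_i alpha_i y_i x_i` over the support vectors, oriented
#' so that positive weights push toward the +1 (patient) class. For a
#' linear kernel this is the exact primal solution; for the RBF kernel it is
#' the standard pseudo-primal surrogate used to attribute a weight to each
#' connection.
#'
#' @param model a fitted `e1071::svm` model, or a fit object from this
#'   package's LOOCV internals.
#' @return numeric weight vector of length p.
#' @export
extract_fold_weights <- function(model) {
  if (is.list(model) && !inherits(model, "svm") && !is.null(model$model)) {
    model <- model$model
  }
  if (!inherits(model, "svm")) abort("expected a fitted svm model")
  if (is.null(model$coefs) || is.null(model$SV)) abort("model has no support vectors; was it fitted?")
  w <- as.vector(crossprod(model$coefs, model$SV)) * svm_sign(model)
  w
}

#' Mean classification weights across LOOCV folds
#'
#' @param folds list of per-fold weight vectors, or a folds x p matrix.
#' @return elementwise mean weight vector.
#' @export
mean_classification_weights <- function(folds) {
  if (is.list(folds)) {
    lens <- lengths(folds)
    if (length(unique(lens)) != 1L) abort("fold weight vectors have inconsistent lengths")
    folds <- do.call(rbind, folds)
  }
  if (nrow(folds) < 1L) abort("need at least one fold")
  colMeans(folds)
}

#' Accuracy, sensitivity and specificity of binary predictions
#'
#' Sensitivity is the proportion of +1 (patient) subjects predicted +1;
#' specificity the proportion of -1 (control) subjects predicted -1.
#'
#' @param predictions,labels vectors of +1/-1 of equal length.
#' @return tibble with columns `metric`, `proportion`, and `percent`
#'   (the proportion as a percentage rounded to one decimal).
#' @export
confusion_metrics <- function(predictions, labels) {
  if (length(predictions) == 0L) abort("empty input")
  if (length(predictions) != length(labels)) abort("length mismatch")
  pos <- labels == 1
  tp <- sum(predictions == 1 & pos)
  tn <- sum(predictions == -1 & !pos)
  acc <- (tp + tn) / length(labels)
  sens <- if (any(pos)) tp / sum(pos) else NA_real_
  spec <- if (any(!pos)) tn / sum(!pos) else NA_real_
  tibble::tibble(
    metric = c("accuracy", "sensitivity", "specificity"),
    proportion = c(acc, sens, spec),
    percent = round(100 * c(acc, sens, spec), 1)
  )
}

#' Leave-one-out cross-validated SVM classification
#'
#' Fits one model per subject on the remaining n-1 (standardization
#' statistics from the training fold only), predicts the held-out subject,
#' and aggregates the n predictions. Per-fold weight vectors are extracted
#' with [extract_fold_weights()] and averaged.
#'
#' @param table feature table restricted to the selected connections.
#' @param cfg [svm_config()].
#' @param selection optional [boruta_config()]; when given, selection is
#'   re-run inside every training fold (nested mode) and the confirmed
#'   features of that fold are used.
#' @return object of class `classification_report`: `folds` tibble
#'   (subject, observed, predicted, decision value), `metrics`,
#'   `mean_weights`, `fold_weights`, `config`.
#' @export
loocv_classify <- function(table, cfg = svm_config(), selection = NULL) {
  X <- ft_feature_matrix(table)
  y <- ft_labels(table)
  n <- nrow(X)
  if (n < 4L) abort("need at least 4 subjects for LOOCV")
  if (min(sum(y == 1), sum(y == -1)) < 2L) {
    abort("each class needs at least 2 subjects")
  }
  if (ncol(X) < 1L) abort("need at least one selected connection")
  nested <- !is.null(selection)

  preds <- integer(n); dvs <- numeric(n)
  wlist <- vector("list", n)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) abort("training fold contains a single class")
    Xtr <- X[-i, , drop = FALSE]
    keep <- seq_len(ncol(X))
    if (nested) {
      sub <- new_feature_table(Xtr, table$subject_id[-i], ytr,
                               connections = ft_connections(table))
      bres <- run_boruta(sub, selection)
      keep <- which(bres$decision == "confirmed")
      if (length(keep) == 0L) {
        abort("nested selection confirmed no features in a training fold")
      }
      Xtr <- Xtr[, keep, drop = FALSE]
    }
    fit <- fit_svm(Xtr, ytr, cfg)
    pr <- predict_svm(fit, X[i, keep, drop = FALSE])
    preds[i] <- pr$label
    dvs[i] <- pr$decision_value
    w <- rep(0, ncol(X))
    w[keep] <- extract_fold_weights(fit$model)
    wlist[[i]] <- w
  }
  W <- do.call(rbind, wlist)
  colnames(W) <- colnames(X)
  structure(
    list(
      folds = tibble::tibble(
        subject_id = table$subject_id, observed = y,
        predicted = preds, decision_value = dvs,
        correct = preds == y
      ),
      metrics = confusion_metrics(preds, y),
      fold_weights = W,
      mean_weights = mean_classification_weights(W),
      features = colnames(X),
      config = cfg,
      nested_selection = nested
    ),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "LOOCV over %d subjects on %d connection(s): accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
    nrow(x$folds), length(x$features),
    m$percent[m$metric == "accuracy"], m$percent[m$metric == "sensitivity"],
    m$percent[m$metric == "specificity"]
  ))
  if (!is.null(x$permutation)) {
    cat(sprintf("permutation test: %d permutations, p = %.4g\n",
                length(x$permutation$null_accuracies), x$permutation$p_value))
  }
  invisible(x)
}

#' Tidy per-fold LOOCV results
#'
#' @param x `classification_report`.
#' @param ... unused.
#' @return the per-fold tibble.
#' @export
tidy.classification_report <- function(x, ...) x$folds

#' @rdname tidy.classification_report
#' @export
glance.classification_report <- function(x, ...) {
  m <- setNames(x$metrics$proportion, x$metrics$metric)
  out <- tibble::tibble(
    n_subjects = nrow(x$folds),
    n_features = length(x$features),
    accuracy = m[["accuracy"]],
    sensitivity = m[["sensitivity"]],
    specificity = m[["specificity"]]
  )
  if (!is.null(x$permutation)) {
    out$p_value <- x$permutation$p_value
    out$n_perm <- length(x$permutation$null_accuracies)
  }
  out
}

#' Label-permutation test of classification accuracy
#'
#' Redraws the class labels uniformly, reruns the full LOOCV on the permuted
#' labels (optionally repeating feature selection inside every permutation),
#' and compares the observed accuracy with the null accuracies via the
#' add-one Monte-Carlo formula `p = (1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param table feature table restricted to the selected connections.
#' @param cfg [svm_config()].
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed for the permutations.
#' @param selection_mode `"once"` (default; the feature set is fixed, as when
#'   selection was run once on the full sample) or `"nested"` (selection
#'   rerun inside every permutation and fold; requires `boruta_cfg`).
#' @param boruta_cfg [boruta_config()] for nested mode.
#' @param observed_accuracy optionally, a precomputed observed accuracy (a
#'   proportion); when NULL the observed LOOCV is run here.
#' @return list with `p_value`, `observed_accuracy`, `null_accuracies`.
#' @export
permutation_test <- function(table, cfg = svm_config(), n_perm = 10000,
                             seed = 1L, selection_mode = c("once", "nested"),
                             boruta_cfg = NULL, observed_accuracy = NULL) {
  selection_mode <- match.arg(selection_mode)
  if (n_perm < 1) abort("n_perm must be at least 1")
  if (selection_mode == "nested" && is.null(boruta_cfg)) {
    abort("nested selection_mode requires boruta_cfg")
  }
  y <- ft_labels(table)
  sel <- if (selection_mode == "nested") boruta_cfg else NULL
  if (is.null(observed_accuracy)) {
    obs_rep <- loocv_classify(table, cfg, selection = sel)
    observed_accuracy <- obs_rep$metrics$proportion[obs_rep$metrics$metric == "accuracy"]
  }
  null_acc <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      yp <- sample(y)   # permuting preserves the class counts (>= 2 each)
      tb <- table
      tb$label <- yp
      rep_b <- loocv_classify(tb, cfg, selection = sel)
      rep_b$metrics$proportion[rep_b$metrics$metric == "accuracy"]
    }, numeric(1))
  })
  list(
    p_value = (1 + sum(null_acc >= observed_accuracy)) / (n_perm + 1),
    observed_accuracy = observed_accuracy,
    null_accuracies = null_acc,
    selection_mode = selection_mode
  )
}

#' Permutation-null histogram
#'
#' Histogram of null accuracies with the observed accuracy marked, the
#' standard display for a label-permutation test of classifier performance.
#'
#' @param object `classification_report` carrying a `$permutation` element,
#'   or the list returned by [permutation_test()].
#' @param ... unused.
#' @return ggplot object.
#' @export
autoplot.classification_report <- function(object, ...) {
  perm <- if (!is.null(object$permutation)) object$permutation else object
  if (is.null(perm$null_accuracies)) abort("no permutation results to plot")
  df <- tibble::tibble(accuracy = perm$null_accuracies)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = perm$observed_accuracy,
                        colour = "red", linewidth = 1) +
    ggplot2::labs(x = "null classification accuracy", y = "count",
                  title = sprintf("Permutation distribution (p = %.4g)", perm$p_value))
}
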