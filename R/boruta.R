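# All-relevant feature selection with shadow features: each iteration
# shuffles every active feature into a shadow copy, fits a tree ensemble on
# [real, shadow], counts a "hit" for a real feature whose Gini importance
# exceeds the 95th percentile of the shadow importances, and decides
# confirmed/rejected by accumulated binomial hit tests with a two-step
# (Benjamini-Hochberg + Bonferroni) correction. Rejected features are
# dropped from the design; iteration ends when nothing is undecided or the
# iteration cap is reached.

#' Boruta configuration
#'
#' @param n_trees trees per random-forest fit (default 500).
#' @param max_iter iteration cap (default 250).
#' @param hit_percentile percentile of shadow importances a real feature
#'   must exceed to score a hit (default 95; linear interpolation between
#'   order statistics).
#' @param alpha significance level of the hit tests (default 0.05).
#' @param null_hit_prob binomial null hit probability (default 0.5, the
#'   convention of the reference all-relevant implementation; 0.05 is
#'   selectable for the reading in which a hit is itself a 5% event).
#' @param correction `"two_step_fdr_bonferroni"` (default; a feature changes
#'   state only when significant under both the BH-corrected and the
#'   Bonferroni-corrected test), `"bonferroni_only"`, or `"none"`.
#' @param seed integer master seed for the run.
#' @return a `boruta_config` list.
#' @export
boruta_config <- function(n_trees = 500, max_iter = 250, hit_percentile = 95,
                          alpha = 0.05, null_hit_prob = 0.5,
                          correction = c("two_step_fdr_bonferroni",
                                         "bonferroni_only", "none"),
                          seed = 1L) {
  correction <- match.arg(correction)
  stopifnot(n_trees >= 1, max_iter >= 1,
            hit_percentile > 0, hit_percentile <= 100,
            alpha > 0, alpha < 1,
            null_hit_prob > 0, null_hit_prob < 1)
  structure(
    list(n_trees = as.integer(n_trees), max_iter = as.integer(max_iter),
         hit_percentile = hit_percentile, alpha = alpha,
         null_hit_prob = null_hit_prob, correction = correction,
         seed = as.integer(seed)),
    class = "boruta_config"
  )
}

#' Shadow features: columnwise permutations
#'
#' Shuffles each column of `A` across subjects independently, destroying any
#' association with the class labels while preserving each feature's
#' marginal distribution. Fresh permutations are drawn on every call.
#'
#' @param A numeric matrix, n subjects x p features, n >= 2.
#' @param seed optional seed for a reproducible draw (the selection loop
#'   passes per-iteration seeds derived from its master seed).
#' @return n x p matrix; column k is a permutation of column k of `A`.
#' @export
make_shadow_features <- function(A, seed = NULL) {
  A <- as.matrix(A)
  if (nrow(A) < 2L || ncol(A) < 1L) abort("need at least 2 rows and 1 column")
  draw <- function() apply(A, 2L, sample)
  B <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  colnames(B) <- paste0("shadow_", colnames(A) %||% seq_len(ncol(A)))
  B
}

#' Gini importance of a feature matrix
#'
#' Mean decrease in Gini impurity per feature over an ensemble of
#' bootstrap-sampled, feature-subsampled classification trees, normalised to
#' sum to one. Tree fitting is delegated to ranger; the contract here is the
#' importance semantics.
#'
#' @param C numeric matrix n x m (typically the mixture `[A, shadow(A)]`).
#' @param labels class labels (+1/-1), both classes present.
#' @param n_trees ensemble size.
#' @param seed forest seed.
#' @return nonnegative numeric vector of length m summing to 1.
#' @export
ensemble_importance <- function(C, labels, n_trees = 500, seed = 1L) {
  C <- as.matrix(C)
  check_binary_labels(labels)
  if (is.null(colnames(C))) colnames(C) <- paste0("f", seq_len(ncol(C)))
  fit <- ranger::ranger(
    x = C, y = factor(labels),
    num.trees = n_trees, importance = "impurity",
    seed = seed, num.threads = 1L, verbose = FALSE
  )
  imp <- pmax(fit$variable.importance, 0)
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  unname(imp)
}

#' Update hit counts from one iteration's importances
#'
#' A real feature scores a hit when its importance strictly exceeds the
#' `hit_percentile` percentile (linear interpolation between order
#' statistics) of the shadow importances.
#'
#' @param importances length-2p vector: first p real features, last p shadows.
#' @param hits length-p integer vector of accumulated hits.
#' @param hit_percentile percentile in (0, 100].
#' @return updated hit vector.
#' @export
update_hits <- function(importances, hits, hit_percentile = 95) {
  p <- length(hits)
  if (p == 0L) abort("no features")
  if (length(importances) != 2L * p) {
    abort("importances must have length 2 * length(hits)")
  }
  thr <- quantile(importances[(p + 1L):(2L * p)], probs = hit_percentile / 100,
                  type = 7, names = FALSE)
  hits + as.integer(importances[seq_len(p)] > thr)
}

# Exact binomial tail probabilities of the accumulated hit counts, by
# direct summation of the mass function (a complement like 1 - cdf loses
# exactness at the tail boundary).
binom_tails <- function(hits, n_iter, null_hit_prob) {
  list(
    upper = vapply(hits, function(h) {
      sum(dbinom(h:n_iter, n_iter, null_hit_prob))
    }, numeric(1)),
    lower = vapply(hits, function(h) {
      sum(dbinom(0:h, n_iter, null_hit_prob))
    }, numeric(1))
  )
}

# Decide states for the currently undecided family. `m_bonf` is the feature
# count dividing alpha in the Bonferroni step. Two-step = BH AND Bonferroni.
decide_states <- function(hits, n_iter, cfg, m_bonf = length(hits)) {
  if (any(hits > n_iter)) abort("hits cannot exceed the number of iterations")
  tails <- binom_tails(hits, n_iter, cfg$null_hit_prob)
  # tolerance absorbs ulp-level error of the tail sum when it lands exactly
  # on the significance boundary in real arithmetic (e.g. P = alpha)
  eps <- 1e-12
  sig <- function(p) {
    switch(cfg$correction,
      none = p <= cfg$alpha + eps,
      bonferroni_only = p <= cfg$alpha / m_bonf + eps,
      two_step_fdr_bonferroni =
        (stats::p.adjust(p, method = "BH") <= cfg$alpha + eps) &
        (p <= cfg$alpha / m_bonf + eps)
    )
  }
  confirm <- sig(tails$upper)
  reject <- sig(tails$lower) & !confirm
  out <- rep("undecided", length(hits))
  out[confirm] <- "confirmed"
  out[reject] <- "rejected"
  out
}

#' Binomial hit-count decision for a single feature
#'
#' Confirms when the exact upper-tail probability P(X >= hits) under
#' Binomial(n_iter, null_hit_prob) is significant, rejects when the lower
#' tail P(X <= hits) is, and returns `"undecided"` otherwise. The correction
#' in `cfg` is applied with family size `m` (for one feature in isolation a
#' Bonferroni family of 1 reduces to the plain test).
#'
#' @param hits accumulated hit count(s), 0 <= hits <= n_iter.
#' @param n_iter number of completed iterations (trials).
#' @param cfg [boruta_config()].
#' @param m correction family size (default `length(hits)`).
#' @return character vector in {"confirmed", "rejected", "undecided"}.
#' @export
binomial_decision <- function(hits, n_iter, cfg = boruta_config(), m = length(hits)) {
  stopifnot(n_iter >= 1, all(hits >= 0))
  decide_states(hits, n_iter, cfg, m_bonf = m)
}

#' Run the all-relevant selection loop
#'
#' @param table feature table (`subject_id`, `label`, feature columns).
#' @param cfg [boruta_config()].
#' @return object of class `boruta_result` with elements `decision`
#'   (confirmed / rejected / tentative per feature), `hits`, `n_iter_run`,
#'   `importance_history` (iterations x 2p, NA once a feature is removed),
#'   `confirmed_index` (tibble of confirmed connections), `config`,
#'   `feature_names`.
#' @export
run_boruta <- function(table, cfg = boruta_config()) {
  X <- ft_feature_matrix(table)
  labels <- ft_labels(table)
  check_binary_labels(labels)
  if (nrow(X) < 4L) abort("need at least 4 subjects")
  sds <- apply(X, 2L, sd)
  if (all(sds == 0)) abort("degenerate feature table: every feature is constant")
  p <- ncol(X)
  feature_names <- colnames(X)

  state <- rep("undecided", p)
  hits <- integer(p)
  hist_list <- vector("list", cfg$max_iter)
  n_iter_run <- 0L

  withr::with_seed(cfg$seed, {
    for (it in seq_len(cfg$max_iter)) {
      n_iter_run <- it
      active <- which(state != "rejected")
      A_act <- X[, active, drop = FALSE]
      B <- apply(A_act, 2L, sample)        # fresh shadows every iteration
      C <- cbind(A_act, B)
      colnames(C) <- c(feature_names[active],
                       paste0("shadow_", feature_names[active]))
      it_seed <- sample.int(2147483629L, 1L)
      imp <- ensemble_importance(C, labels, n_trees = cfg$n_trees, seed = it_seed)
      pa <- length(active)
      hits[active] <- update_hits(imp, hits[active], cfg$hit_percentile)

      row <- rep(NA_real_, 2L * p)
      row[active] <- imp[seq_len(pa)]
      row[p + active] <- imp[pa + seq_len(pa)]
      hist_list[[it]] <- row

      und <- which(state == "undecided")
      new_state <- decide_states(hits[und], it, cfg, m_bonf = length(und))
      state[und] <- new_state
      if (!any(state == "undecided")) break
    }
  })

  state[state == "undecided"] <- "tentative"
  history <- do.call(rbind, hist_list[seq_len(n_iter_run)])
  colnames(history) <- c(feature_names, paste0("shadow_", feature_names))

  conn <- ft_connections(table)
  confirmed_pos <- which(state == "confirmed")
  confirmed_index <- conn[confirmed_pos, , drop = FALSE]

  structure(
    list(
      decision = factor(state, levels = c("confirmed", "rejected", "tentative")),
      hits = setNames(hits, feature_names),
      n_iter_run = n_iter_run,
      importance_history = history,
      confirmed_index = confirmed_index,
      confirmed_features = feature_names[confirmed_pos],
      config = cfg,
      feature_names = feature_names
    ),
    class = "boruta_result"
  )
}

#' Restrict a feature table to the selected connections
#'
#' @param table the feature table the selection was run on.
#' @param result `boruta_result`.
#' @param include_tentative also keep tentative features (default FALSE:
#'   confirmed only, since only definitively relevant connections are fed
#'   to the classifier).
#' @return feature table with only the selected connection columns.
#' @export
select_confirmed <- function(table, result, include_tentative = FALSE) {
  states <- if (include_tentative) c("confirmed", "tentative") else "confirmed"
  keep <- which(result$decision %in% states)
  if (length(keep) == 0L) abort("no connections selected")
  new_feature_table(
    ft_feature_matrix(table)[, keep, drop = FALSE],
    table$subject_id, ft_labels(table),
    connections = ft_connections(table)[keep, , drop = FALSE]
  )
}

#' @export
print.boruta_result <- function(x, ...) {
  tab <- table(x$decision)
  cat("All-relevant selection over", length(x$decision), "features\n")
  cat(sprintf("  confirmed %d, rejected %d, tentative %d after %d iteration(s)\n",
              tab[["confirmed"]], tab[["rejected"]], tab[["tentative"]],
              x$n_iter_run))
  invisible(x)
}

#' Tidy a selection result
#'
#' @param x `boruta_result`.
#' @param ... unused.
#' @return tibble with one row per feature: `feature`, `decision`, `hits`,
#'   `hit_rate`, `mean_importance`.
#' @export
tidy.boruta_result <- function(x, ...) {
  mi <- colMeans(x$importance_history[, x$feature_names, drop = FALSE], na.rm = TRUE)
  tibble::tibble(
    feature = x$feature_names,
    decision = as.character(x$decision),
    hits = as.integer(x$hits),
    hit_rate = x$hits / x$n_iter_run,
    mean_importance = unname(mi)
  )
}

#' @rdname tidy.boruta_result
#' @export
glance.boruta_result <- function(x, ...) {
  tab <- table(x$decision)
  tibble::tibble(
    n_features = length(x$decision),
    n_confirmed = as.integer(tab[["confirmed"]]),
    n_rejected = as.integer(tab[["rejected"]]),
    n_tentative = as.integer(tab[["tentative"]]),
    n_iter_run = x$n_iter_run
  )
}

#' Importance-history plot of a selection run
#'
#' Per-iteration Gini importances of confirmed features against the shadow
#' envelope (the hit-percentile threshold of the shadow importances).
#'
#' @param object `boruta_result`.
#' @param ... unused.
#' @return ggplot object.
#' @export
autoplot.boruta_result <- function(object, ...) {
  p <- length(object$feature_names)
  hist <- object$importance_history
  shadow <- hist[, p + seq_len(p), drop = FALSE]
  pct <- object$config$hit_percentile / 100
  thr <- apply(shadow, 1L, function(r) quantile(r, pct, na.rm = TRUE, names = FALSE))
  df <- tibble::as_tibble(hist[, seq_len(p), drop = FALSE]) |>
    dplyr::mutate(iteration = dplyr::row_number()) |>
    tidyr::pivot_longer(-"iteration", names_to = "feature", values_to = "importance") |>
    dplyr::left_join(
      tibble::tibble(feature = object$feature_names,
                     decision = as.character(object$decision)),
      by = "feature"
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$importance,
                                   group = .data$feature, colour = .data$decision)) +
    ggplot2::geom_line(alpha = 0.4, na.rm = TRUE) +
    ggplot2::geom_line(
      data = tibble::tibble(iteration = seq_along(thr), importance = thr),
      ggplot2::aes(x = .data$iteration, y = .data$importance),
      inherit.aes = FALSE, linewidth = 1, colour = "black", linetype = 2
    ) +
    ggplot2::labs(x = "iteration", y = "normalised Gini importance",
                  colour = "decision",
                  title = "Feature importances vs shadow threshold (dashed)")
}

#' Serialize a selection result
#'
#' Writes decisions/hits/config as JSON and the importance history as CSV.
#'
#' @param x `boruta_result`.
#' @param json_path,history_path output paths (either may be NULL to skip).
#' @export
write_boruta_result <- function(x, json_path, history_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(
        decisions = setNames(as.character(x$decision), x$feature_names),
        hits = as.list(x$hits),
        n_iter_run = x$n_iter_run,
        confirmed = x$confirmed_features,
        config = unclass(x$config)
      ),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  if (!is.null(history_path)) {
    readr::write_csv(tibble::as_tibble(x$importance_history), history_path,
                     progress = FALSE)
  }
  invisible(x)
}
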