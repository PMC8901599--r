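# Brain-behaviour association: per-connection classification scores and
# their Pearson correlation with clinical symptom scales in the patient
# group.

# The five canonical symptom-scale columns.
CLINICAL_SCALES <- c("ADI_R_social", "ADI_R_verbal", "ADOS_total",
                     "ADOS_communication", "ADOS_social")

#' Per-connection classification scores
#'
#' The classification score of connection c in subject i is defined as
#' `mean_weight_c * z_ic`, the product of the connection's mean LOOCV
#' classification weight and the subject's standardized feature value:
#' the connection's additive contribution to the (pseudo-)primal decision
#' value. Standardization is per feature across the subjects in `table`.
#'
#' @param table feature table restricted to the selected connections.
#' @param mean_weights mean classification weights aligned to the feature
#'   columns of `table`.
#' @return tibble: `subject_id` plus one numeric score column per
#'   connection.
#' @export
classification_scores <- function(table, mean_weights) {
  X <- ft_feature_matrix(table)
  if (length(mean_weights) != ncol(X)) {
    abort("mean_weights length does not match the number of connections")
  }
  if (!is.null(names(mean_weights)) &&
      !identical(names(mean_weights), colnames(X))) {
    abort("mean_weights names do not align with the connection columns")
  }
  sds <- apply(X, 2L, sd)
  sds[sds == 0] <- 1
  Z <- sweep(sweep(X, 2L, colMeans(X), "-"), 2L, sds, "/")
  S <- sweep(Z, 2L, as.numeric(mean_weights), "*")
  dplyr::bind_cols(tibble::tibble(subject_id = table$subject_id),
                   tibble::as_tibble(as.data.frame(S, check.names = FALSE)))
}

#' Correlate classification scores with clinical scales
#'
#' Pearson correlation of each (connection, scale) pair over the patient
#' subjects present in both tables, with two-sided p-values from the
#' t-distribution (n - 2 df) and pairwise deletion of missing scale values.
#' Pairs with fewer than 3 complete observations, or with a constant score
#' or scale vector, are reported with `NA` r and a note rather than being
#' dropped silently.
#'
#' @param scores output of [classification_scores()] (patients only).
#' @param clinical tibble with `subject_id` and scale columns (any subset of
#'   `ADI_R_social`, `ADI_R_verbal`, `ADOS_total`, `ADOS_communication`,
#'   `ADOS_social`); missing values allowed.
#' @param alpha significance threshold (default 0.05).
#' @param correction `"none"` (default, matching uncorrected per-pair
#'   reporting) or `"bh"` for Benjamini-Hochberg across all pairs.
#' @return tibble of class `correlation_result`: `connection`, `scale`,
#'   `n_used`, `r`, `p` (plus `p_adj` under BH), `sign`, `significant`,
#'   `note`.
#' @export
correlate_with_scales <- function(scores, clinical, alpha = 0.05,
                                  correction = c("none", "bh")) {
  correction <- match.arg(correction)
  scales <- intersect(CLINICAL_SCALES, names(clinical))
  if (length(scales) == 0) abort("clinical table has no recognised scale columns")
  merged <- dplyr::inner_join(scores, clinical, by = "subject_id")
  if (nrow(merged) == 0) abort("no overlapping subjects between scores and clinical table")
  conns <- setdiff(names(scores), "subject_id")
  grid <- tidyr::expand_grid(connection = conns, scale = scales)
  out <- purrr::pmap_dfr(grid, function(connection, scale) {
    x <- merged[[connection]]
    y <- merged[[scale]]
    ok <- complete.cases(x, y)
    n_used <- sum(ok)
    if (n_used < 3) {
      return(tibble::tibble(connection, scale, n_used, r = NA_real_,
                            p = NA_real_, note = "fewer than 3 complete pairs"))
    }
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(tibble::tibble(connection, scale, n_used, r = NA_real_,
                            p = NA_real_, note = "constant vector; correlation undefined"))
    }
    ct <- cor.test(x[ok], y[ok], method = "pearson", alternative = "two.sided")
    tibble::tibble(connection, scale, n_used,
                   r = unname(ct$estimate), p = ct$p.value, note = NA_character_)
  })
  if (correction == "bh") {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  } else {
    out$significant <- !is.na(out$p) & out$p < alpha
  }
  out$sign <- dplyr::case_when(
    is.na(out$r) ~ NA_character_,
    out$r >= 0 ~ "positive",
    TRUE ~ "negative"
  )
  class(out) <- c("correlation_result", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "correction") <- correction
  out
}

#' @export
tidy.correlation_result <- function(x, ...) tibble::as_tibble(x)

#' @rdname correlate_with_scales
#' @param x `correlation_result`.
#' @param ... unused.
#' @export
glance.correlation_result <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    n_positive = sum(x$significant & x$sign == "positive", na.rm = TRUE),
    n_negative = sum(x$significant & x$sign == "negative", na.rm = TRUE),
    alpha = attr(x, "alpha")
  )
}

#' Plot significant brain-behaviour correlations
#'
#' r-values of the significant (connection, scale) pairs, split by sign.
#'
#' @param object `correlation_result`.
#' @param ... unused.
#' @return ggplot object.
#' @export
autoplot.correlation_result <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$significant)
  if (nrow(df) == 0) {
    df <- tibble::as_tibble(object) |> dplyr::filter(!is.na(.data$r))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r,
                                   y = stats::reorder(paste(.data$connection, .data$scale, sep = " / "), .data$r),
                                   fill = .data$sign)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Pearson r (classification score vs scale)", y = NULL,
                  fill = "sign")
}
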