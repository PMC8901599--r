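# Fixtures are generated in code; no data files.

# Small planted dataset mirroring the study shape at reduced scale:
# R = 25 ROIs -> 300 connections, 48 + 50 subjects by default.
planted_config <- function(seed, n_patients = 48, n_controls = 50, R = 25,
                           n_discriminative = 20, effect_size = 1.5,
                           n_clinical_linked = 5, r_clin = 0.6, ...) {
  synthetic_config(
    seed = seed, n_patients = n_patients, n_controls = n_controls, R = R,
    n_discriminative = n_discriminative, effect_size = effect_size,
    n_clinical_linked = n_clinical_linked, r_clin = r_clin, ...
  )
}

noise_config <- function(seed, n_patients = 48, n_controls = 50, R = 25) {
  synthetic_config(seed = seed, n_patients = n_patients,
                   n_controls = n_controls, R = R,
                   n_discriminative = 0, effect_size = 0,
                   n_clinical_linked = 0)
}

quick_boruta <- function(seed, n_trees = 100, max_iter = 50, ...) {
  boruta_config(n_trees = n_trees, max_iter = max_iter, seed = seed, ...)
}

# Feature table built directly from a matrix (bypasses the generator).
matrix_table <- function(X, labels, ids = sprintf("S%03d", seq_len(nrow(X)))) {
  colnames(X) <- colnames(X) %||% sprintf("ROI%02da--ROI%02db", seq_len(ncol(X)), seq_len(ncol(X)))
  borutafc:::new_feature_table(
    X, ids, labels,
    connections = tibble::tibble(name = colnames(X))
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Exact binomial tail-sum oracle by explicit summation (independent of
# stats::pbinom): P(X >= h) and P(X <= h) under Binomial(n, p0).
oracle_tails <- function(h, n, p0) {
  k <- 0:n
  pk <- choose(n, k) * p0^k * (1 - p0)^(n - k)
  list(upper = sum(pk[k >= h]), lower = sum(pk[k <= h]))
}

oracle_decision <- function(h, n, p0, alpha = 0.05) {
  t <- oracle_tails(h, n, p0)
  if (t$upper <= alpha) "confirmed" else if (t$lower <= alpha) "rejected" else "undecided"
}
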