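#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% abort warn .data
#' @importFrom stats cor cor.test dbinom pbinom quantile sd var kmeans dist
#'   rnorm runif setNames complete.cases
#' @importFrom utils head
NULL

# The six canonical resting-state networks of the functional atlas.
FC_NETWORKS <- c("DMN", "FPN", "CON", "SMN", "ON", "CN")

# Deterministic per-stage substreams derived from one master seed, so that
# every stage is reproducible on its own and stages do not share RNG state.
SEED_OFFSETS <- c(
  atlas = 11, features = 23, timeseries = 37, clinical = 41,
  boruta = 53, svm = 67, permutation = 79, patterns = 97
)

sub_seed <- function(seed, stream) {
  if (!stream %in% names(SEED_OFFSETS)) {
    abort(paste0("unknown seed substream '", stream, "'"))
  }
  # double arithmetic to avoid 32-bit overflow; result fits in an R integer
  as.integer((as.numeric(seed) * 101 + SEED_OFFSETS[[stream]]) %% 2147483629)
}

#' Row-major upper-triangle connection index
#'
#' Enumerates all ROI pairs (i, j), i < j, in the fixed row-major order
#' (1,2), (1,3), ..., (1,R), (2,3), ..., (R-1,R). This ordering is written
#' into every output file and is the contract for all connection vectors.
#'
#' @param R number of ROIs (>= 2)
#' @param roi_names optional character vector of length R; when given, a
#'   `name` column `"<roiA>--<roiB>"` is added.
#' @return tibble with integer columns `i`, `j` (1-based ROI positions) and,
#'   optionally, `name`.
#' @export
connection_index <- function(R, roi_names = NULL) {
  stopifnot(is.numeric(R), length(R) == 1, R >= 2)
  R <- as.integer(R)
  i <- rep.int(seq_len(R - 1L), times = (R - 1L):1L)
  j <- unlist(lapply(seq_len(R - 1L), function(k) seq.int(k + 1L, R)))
  out <- tibble::tibble(i = i, j = as.integer(j))
  if (!is.null(roi_names)) {
    stopifnot(length(roi_names) == R)
    out$name <- paste0(roi_names[out$i], "--", roi_names[out$j])
  }
  out
}

# matrix of feature columns from a feature table (everything except the
# subject_id / label bookkeeping columns)
ft_feature_matrix <- function(table) {
  meta <- intersect(c("subject_id", "label"), names(table))
  X <- as.matrix(table[setdiff(names(table), meta)])
  storage.mode(X) <- "double"
  rownames(X) <- table$subject_id
  X
}

ft_labels <- function(table) {
  if (!"label" %in% names(table)) abort("feature table has no 'label' column")
  lab <- as.integer(table$label)
  if (!all(lab %in% c(-1L, 1L))) {
    abort("labels must be +1 (patients) / -1 (controls)")
  }
  lab
}

check_binary_labels <- function(labels) {
  if (length(unique(labels)) < 2L) abort("both classes must be present")
  invisible(labels)
}
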