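# Construction of the whole-brain interregional functional-connectivity
# feature table: Pearson correlation of ROI time series, Fisher r-to-z,
# upper-triangle vectorization, and assembly across subjects.

#' Pearson functional-connectivity matrix of one subject
#'
#' Computes the R x R matrix of Pearson correlation coefficients between the
#' average ROI time series (columns of `ts`). The result is exactly
#' symmetric with unit diagonal.
#'
#' @param ts numeric matrix, T timepoints x R ROIs, T >= 3, no missing
#'   values; column names are ROI names.
#' @return numeric R x R matrix with attribute `fc_scale = "pearson_r"`.
#' @export
#' @examples
#' ts <- cbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4), c = c(4, 3, 2, 1))
#' compute_fc_matrix(ts)
compute_fc_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L) abort("need at least 3 timepoints to correlate")
  if (ncol(ts) < 2L) abort("need at least 2 ROIs")
  if (anyNA(ts)) abort("time series contain missing values")
  sds <- apply(ts, 2L, sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0] %||% which(sds == 0)
    abort(paste0(
      "zero-variance time series for ROI(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  m <- cor(ts)
  m <- (m + t(m)) / 2   # enforce exact symmetry
  diag(m) <- 1
  attr(m, "fc_scale") <- "pearson_r"
  m
}

#' Fisher r-to-z transformation
#'
#' Applies z = atanh(r) elementwise, after clipping |r| to 1 - 1e-7 so the
#' transform stays finite for perfectly correlated series. For a matrix the
#' diagonal is set to 0 (self-connections are excluded from features).
#'
#' @param m correlation matrix from [compute_fc_matrix()], or a numeric
#'   vector of r values.
#' @return same shape as the input on the z scale (`fc_scale = "fisher_z"`).
#' @export
fisher_z <- function(m) {
  if (identical(attr(m, "fc_scale"), "fisher_z")) {
    abort("input is already on the Fisher-z scale")
  }
  r <- pmin(pmax(unclass(m), -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  if (is.matrix(m)) {
    diag(z) <- 0
    dimnames(z) <- dimnames(m)
  }
  attr(z, "fc_scale") <- "fisher_z"
  z
}

#' Extract the upper triangle of a connectivity matrix
#'
#' Vectorizes the strictly-upper-triangular part of a square symmetric
#' matrix in the fixed row-major order of [connection_index()].
#'
#' @param m square symmetric numeric matrix.
#' @return list with `values` (length R(R-1)/2) and `connections` (the
#'   [connection_index()] tibble, with names when `m` has dimnames).
#' @export
vectorize_upper_triangle <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) abort("input must be a square matrix")
  idx <- connection_index(nrow(m), roi_names = rownames(m))
  values <- m[cbind(idx$i, idx$j)]
  if ("name" %in% names(idx)) names(values) <- idx$name
  list(values = values, connections = idx)
}

#' Re-fold a connection vector into a symmetric matrix
#'
#' Inverse of [vectorize_upper_triangle()] for the off-diagonal part; the
#' diagonal is filled with `diag_value`.
#'
#' @param values connection vector in row-major upper-triangle order.
#' @param R number of ROIs.
#' @param diag_value diagonal fill (default 0).
#' @param roi_names optional dimnames.
#' @return R x R symmetric matrix.
#' @export
fold_connectivity <- function(values, R, diag_value = 0, roi_names = NULL) {
  idx <- connection_index(R)
  if (length(values) != nrow(idx)) {
    abort("length(values) must equal R*(R-1)/2")
  }
  m <- matrix(diag_value, R, R)
  m[cbind(idx$i, idx$j)] <- values
  m[cbind(idx$j, idx$i)] <- values
  if (!is.null(roi_names)) dimnames(m) <- list(roi_names, roi_names)
  m
}

#' Assemble the subjects x connections feature table
#'
#' Runs [compute_fc_matrix()] -> [fisher_z()] -> [vectorize_upper_triangle()]
#' for every subject and stacks the resulting Fisher-z connection vectors
#' into one table, one row per subject, one column per ROI pair.
#'
#' @param ts_list named list of time-series matrices (names are subject ids),
#'   all with the same ROI columns as `atlas`.
#' @param atlas ROI atlas tibble (see [read_atlas()]).
#' @param labels tibble with columns `subject_id` and `label` (+1 patients,
#'   -1 controls), or a named vector.
#' @return a feature-table tibble: `subject_id`, `label`, then one numeric
#'   column per connection named `"<roiA>--<roiB>"`; the connection index is
#'   attached as attribute `"connections"`.
#' @export
assemble_feature_table <- function(ts_list, atlas, labels) {
  validate_atlas(atlas)
  ids <- names(ts_list)
  if (is.null(ids) || anyDuplicated(ids)) {
    abort("ts_list must be named by unique subject ids")
  }
  if (!is.data.frame(labels)) {
    labels <- tibble::tibble(subject_id = names(labels), label = as.integer(labels))
  }
  missing_lab <- setdiff(ids, labels$subject_id)
  if (length(missing_lab) > 0) {
    abort(paste0("missing labels for subject(s): ", paste(missing_lab, collapse = ", ")))
  }
  R <- nrow(atlas)
  rows <- lapply(ids, function(id) {
    ts <- as.matrix(ts_list[[id]])
    if (ncol(ts) != R) {
      abort(paste0("subject ", id, " has ", ncol(ts), " ROIs; atlas has ", R))
    }
    colnames(ts) <- atlas$name
    vectorize_upper_triangle(fisher_z(compute_fc_matrix(ts)))$values
  })
  feats <- do.call(rbind, rows)
  conn <- connection_index(R, roi_names = atlas$name)
  colnames(feats) <- conn$name
  lab <- labels$label[match(ids, labels$subject_id)]
  new_feature_table(feats, subject_id = ids, label = as.integer(lab),
                    connections = conn)
}

new_feature_table <- function(features, subject_id, label, connections) {
  out <- tibble::as_tibble(as.data.frame(features, check.names = FALSE))
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = subject_id, label = as.integer(label)), out
  )
  attr(out, "connections") <- connections
  class(out) <- c("fc_table", class(out))
  out
}

# Recover the connection index of a feature table: prefer the attribute,
# otherwise parse "<roiA>--<roiB>" column names against the atlas.
ft_connections <- function(table, atlas = NULL) {
  conn <- attr(table, "connections")
  if (!is.null(conn)) return(conn)
  nms <- setdiff(names(table), c("subject_id", "label"))
  parts <- stringr::str_split_fixed(nms, "--", 2)
  if (any(parts[, 2] == "")) abort("cannot parse connection names; expected '<roiA>--<roiB>'")
  out <- tibble::tibble(name = nms)
  if (!is.null(atlas)) {
    out$i <- match(parts[, 1], atlas$name)
    out$j <- match(parts[, 2], atlas$name)
    if (anyNA(out$i) || anyNA(out$j)) abort("connection names do not match atlas ROI names")
    out <- out[, c("i", "j", "name")]
  }
  out
}

#' Validate an ROI atlas
#'
#' An atlas assigns each ROI a unique name, one of the six canonical
#' network labels (DMN, FPN, CON, SMN, ON, CN), and MNI coordinates.
#'
#' @param atlas tibble with columns `roi_id`, `name`, `network`, `x`, `y`, `z`.
#' @return the atlas, invisibly, or an error.
#' @export
validate_atlas <- function(atlas) {
  need <- c("roi_id", "name", "network", "x", "y", "z")
  miss <- setdiff(need, names(atlas))
  if (length(miss) > 0) abort(paste0("atlas lacks column(s): ", paste(miss, collapse = ", ")))
  if (nrow(atlas) < 2) abort("atlas needs at least 2 ROIs")
  ids <- sort(as.integer(atlas$roi_id))
  if (anyDuplicated(ids) || !(identical(ids, seq_len(nrow(atlas)) - 1L) ||
                              identical(ids, seq_len(nrow(atlas))))) {
    abort("roi_id must be unique and contiguous (0- or 1-based)")
  }
  if (anyDuplicated(atlas$name)) abort("ROI names must be unique")
  if (any(grepl("--", atlas$name, fixed = TRUE))) {
    abort("ROI names must not contain '--' (reserved connection separator)")
  }
  bad <- setdiff(unique(atlas$network), FC_NETWORKS)
  if (length(bad) > 0) {
    abort(paste0("unknown network label(s): ", paste(bad, collapse = ", "),
                 "; expected one of ", paste(FC_NETWORKS, collapse = ", ")))
  }
  invisible(atlas)
}

#' Read an ROI atlas from TSV
#'
#' @param path TSV file with header `roi_id, name, network, x, y, z`.
#' @return validated atlas tibble.
#' @export
read_atlas <- function(path) {
  atlas <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_atlas(atlas)
  atlas
}

#' @rdname read_atlas
#' @param atlas atlas tibble.
#' @export
write_atlas <- function(atlas, path) {
  validate_atlas(atlas)
  readr::write_tsv(atlas, path, progress = FALSE)
  invisible(path)
}

#' Read one subject's ROI time series from TSV
#'
#' @param path TSV file, T rows x R columns, header row of ROI names.
#' @param atlas optional atlas; when given, columns are checked against it.
#' @return numeric matrix T x R.
#' @export
read_time_series <- function(path, atlas = NULL) {
  ts <- as.matrix(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
  if (!is.null(atlas)) {
    if (!identical(colnames(ts), atlas$name)) {
      abort(paste0("time-series columns do not match atlas ROI names: ", path))
    }
  }
  ts
}

#' Read a subject manifest
#'
#' @param path CSV with columns `subject_id`, `file`, `label` (+1/-1).
#' @return tibble.
#' @export
read_manifest <- function(path) {
  mf <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "file", "label")
  miss <- setdiff(need, names(mf))
  if (length(miss) > 0) abort(paste0("manifest lacks column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(mf$subject_id)) abort("duplicated subject_id in manifest")
  mf
}

#' Write / read a feature table as CSV
#'
#' The CSV layout is `subject_id, label`, then one column per connection
#' named `"<roiA>--<roiB>"` in row-major upper-triangle order.
#'
#' @param table feature table from [assemble_feature_table()].
#' @param path file path.
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param atlas optional atlas used to rebuild the connection index.
#' @export
read_feature_table <- function(path, atlas = NULL) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  feats <- as.matrix(tb[setdiff(names(tb), c("subject_id", "label"))])
  conn <- tryCatch(
    ft_connections(tb, atlas = atlas),
    error = function(e) NULL
  )
  out <- new_feature_table(feats, tb$subject_id, tb$label,
                           connections = conn %||% tibble::tibble(name = colnames(feats)))
  out
}
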