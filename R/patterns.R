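# Interpretation analytics over the selected connection set: region and
# network classification weights, the 2-SD important-region rule, network
# degree, k-means connection patterns, and within/between-network counts.

#' Build a connection set
#'
#' Bundles the selected connections, their mean classification weights and
#' the atlas into one tibble used by all pattern analytics.
#'
#' @param connections tibble with ROI positions `i`, `j` (i < j) or a `name`
#'   column `"<roiA>--<roiB>"` resolvable against the atlas.
#' @param weights numeric vector of mean classification weights, one per
#'   connection.
#' @param atlas validated ROI atlas.
#' @return tibble of class `connection_set` with columns `i`, `j`, `name`,
#'   `roi_i`, `roi_j`, `network_i`, `network_j`, `weight`; the atlas is
#'   attached as attribute `"atlas"`.
#' @export
connection_set <- function(connections, weights, atlas) {
  validate_atlas(atlas)
  conn <- tibble::as_tibble(connections)
  if (!all(c("i", "j") %in% names(conn))) {
    if (!"name" %in% names(conn)) abort("connections need i/j columns or a name column")
    parts <- stringr::str_split_fixed(conn$name, "--", 2)
    conn$i <- match(parts[, 1], atlas$name)
    conn$j <- match(parts[, 2], atlas$name)
  }
  if (anyNA(conn$i) || anyNA(conn$j)) abort("connection ROI(s) not found in atlas")
  if (any(conn$i < 1 | conn$j < 1 | conn$i > nrow(atlas) | conn$j > nrow(atlas))) {
    abort("connection ROI positions out of range")
  }
  if (any(conn$i >= conn$j)) abort("connections must have i < j")
  key <- paste(conn$i, conn$j)
  if (anyDuplicated(key)) abort("duplicated connections")
  if (length(weights) != nrow(conn)) {
    abort("weight vector length does not match the number of connections")
  }
  out <- tibble::tibble(
    i = as.integer(conn$i), j = as.integer(conn$j),
    roi_i = atlas$name[conn$i], roi_j = atlas$name[conn$j],
    name = paste0(atlas$name[conn$i], "--", atlas$name[conn$j]),
    network_i = atlas$network[conn$i], network_j = atlas$network[conn$j],
    weight = as.numeric(weights)
  )
  attr(out, "atlas") <- atlas
  class(out) <- c("connection_set", class(out))
  out
}

cs_atlas <- function(cs, atlas = NULL) {
  atlas <- atlas %||% attr(cs, "atlas")
  if (is.null(atlas)) abort("no atlas attached to the connection set")
  atlas
}

#' Region classification weights
#'
#' The weight of a brain region is the sum over all selected connections
#' incident to it of the connection weight: |w| in `"absolute"` mode (the
#' default, since importance rankings are magnitude-like) or the raw signed
#' w in `"signed"` mode. ROIs with no incident connection get 0 and are
#' flagged non-contributing.
#'
#' @param cs [connection_set()].
#' @param mode `"absolute"` or `"signed"`.
#' @param atlas optional atlas override.
#' @return tibble: `roi`, `network`, `weight`, `contributing`.
#' @export
region_weights <- function(cs, mode = c("absolute", "signed"), atlas = NULL) {
  mode <- match.arg(mode)
  if (nrow(cs) == 0L) abort("empty connection set")
  atlas <- cs_atlas(cs, atlas)
  w <- if (mode == "absolute") abs(cs$weight) else cs$weight
  acc <- rep(0, nrow(atlas))
  deg <- rep(0L, nrow(atlas))
  for (k in seq_len(nrow(cs))) {
    acc[cs$i[k]] <- acc[cs$i[k]] + w[k]
    acc[cs$j[k]] <- acc[cs$j[k]] + w[k]
    deg[cs$i[k]] <- deg[cs$i[k]] + 1L
    deg[cs$j[k]] <- deg[cs$j[k]] + 1L
  }
  tibble::tibble(
    roi = atlas$name, network = atlas$network,
    weight = acc, contributing = deg > 0L
  )
}

#' Network classification weights
#'
#' Sums region weights within each of the six networks; together the
#' networks partition the regions, so the network weights sum exactly to
#' the region weights.
#'
#' @param region_weight output of [region_weights()].
#' @param atlas atlas (only used to validate network labels).
#' @return tibble: `network`, `weight` (all six networks, zeros included).
#' @export
network_weights <- function(region_weight, atlas = NULL) {
  bad <- setdiff(unique(region_weight$network), FC_NETWORKS)
  if (length(bad) > 0) abort(paste0("unknown network label(s): ", paste(bad, collapse = ", ")))
  sums <- region_weight |>
    dplyr::group_by(.data$network) |>
    dplyr::summarise(weight = sum(.data$weight), .groups = "drop")
  tibble::tibble(network = FC_NETWORKS) |>
    dplyr::left_join(sums, by = "network") |>
    dplyr::mutate(weight = dplyr::coalesce(.data$weight, 0))
}

#' Important regions by the 2-SD rule
#'
#' Among the regions contributing to classification (at least one incident
#' selected connection), flags those whose weight strictly exceeds
#' mean + 2 * SD (sample SD, n-1 denominator) of the contributing regions'
#' weights, sorted descending by weight.
#'
#' @param region_weight output of [region_weights()].
#' @return tibble of the selected regions (`roi`, `network`, `weight`),
#'   with the threshold as attribute `"threshold"`.
#' @export
important_regions <- function(region_weight) {
  contrib <- dplyr::filter(region_weight, .data$contributing)
  if (nrow(contrib) < 2L) abort("need at least 2 contributing regions (SD undefined)")
  thr <- mean(contrib$weight) + 2 * sd(contrib$weight)
  out <- contrib |>
    dplyr::filter(.data$weight > thr) |>
    dplyr::arrange(dplyr::desc(.data$weight)) |>
    dplyr::select("roi", "network", "weight")
  attr(out, "threshold") <- thr
  out
}

#' Network degree of the selected connection set
#'
#' The network degree ND(N) of a network is the number of selected
#' connections with exactly one endpoint in N, i.e. its direct connections
#' to other networks; within-network connections are excluded.
#'
#' @param cs [connection_set()].
#' @return tibble: `network`, `nd` (integer, all six networks).
#' @export
network_degree <- function(cs) {
  nd <- vapply(FC_NETWORKS, function(N) {
    sum(xor(cs$network_i == N, cs$network_j == N))
  }, numeric(1))
  tibble::tibble(network = FC_NETWORKS, nd = as.integer(nd))
}

#' Within- and between-network connection counts
#'
#' A connection is within-network iff both endpoints share a network.
#' Per-network counts attribute a between-network connection to both of its
#' endpoint networks.
#'
#' @param cs [connection_set()].
#' @return list with `per_network` (tibble `network`, `n_within`,
#'   `n_between`) and `totals` (tibble `n_within`, `n_between`, `n_total`).
#' @export
within_between_counts <- function(cs) {
  within <- cs$network_i == cs$network_j
  per <- lapply(FC_NETWORKS, function(N) {
    touch_i <- cs$network_i == N
    touch_j <- cs$network_j == N
    tibble::tibble(
      network = N,
      n_within = sum(within & touch_i),
      n_between = sum(!within & (touch_i | touch_j))
    )
  })
  list(
    per_network = dplyr::bind_rows(per),
    totals = tibble::tibble(
      n_within = sum(within), n_between = sum(!within), n_total = nrow(cs)
    )
  )
}

# k-means++ seeding: first center uniform, then each next center drawn with
# probability proportional to squared distance to the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2L, x[centers[1L], ], "-")^2)
  for (c in seq_len(k - 1L)) {
    if (all(d2 == 0)) {
      # fewer distinct points than centers still needed
      abort("fewer distinct rows than clusters requested")
    }
    nxt <- sample.int(n, 1L, prob = d2)
    centers[c + 1L] <- nxt
    d2 <- pmin(d2, rowSums(sweep(x, 2L, x[nxt, ], "-")^2))
  }
  x[centers, , drop = FALSE]
}

#' k-means pattern decomposition of the selected connections
#'
#' Clusters the rows of the connections x subjects profile matrix with
#' Lloyd's algorithm under Euclidean distance, k-means++ seeding, keeping
#' the best of `n_init` restarts by within-cluster sum of squares.
#' Connections in the same cluster form a pattern that covaries across
#' subjects.
#'
#' @param profile numeric matrix, connections x subjects.
#' @param k number of patterns (default 3).
#' @param seed RNG seed; the result is deterministic given the seed.
#' @param n_init number of seeded restarts (default 100).
#' @return tibble: `connection` (rowname or index), `pattern` (integer
#'   cluster id, clusters relabeled by decreasing size); the winning
#'   `stats::kmeans` fit is attached as attribute `"fit"`.
#' @export
kmeans_patterns <- function(profile, k = 3, seed = 1L, n_init = 100) {
  profile <- as.matrix(profile)
  if (k < 1) abort("k must be at least 1")
  if (k > nrow(profile)) abort("k exceeds the number of connections")
  best <- withr::with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_init)) {
      fit <- tryCatch(
        kmeans(profile, centers = kmeanspp_centers(profile, k),
               algorithm = "Lloyd", iter.max = 100),
        warning = function(w) suppressWarnings(
          kmeans(profile, centers = kmeanspp_centers(profile, k),
                 algorithm = "Lloyd", iter.max = 100)
        )
      )
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    best
  })
  # relabel clusters by decreasing size for a stable presentation
  sizes <- tabulate(best$cluster, nbins = k)
  relabel <- order(order(sizes, decreasing = TRUE))  # old id -> new id
  out <- tibble::tibble(
    connection = rownames(profile) %||% as.character(seq_len(nrow(profile))),
    pattern = as.integer(relabel[best$cluster])
  )
  attr(out, "fit") <- best
  out
}

#' Silhouette scan over candidate pattern counts
#'
#' Mean silhouette width of [kmeans_patterns()] solutions for each k,
#' emitted alongside the default k = 3 so the choice is auditable.
#'
#' @param profile connections x subjects matrix.
#' @param k_range candidate ks (default 2:8, truncated to the row count).
#' @param seed,n_init as in [kmeans_patterns()].
#' @return tibble: `k`, `mean_silhouette`.
#' @export
silhouette_scan <- function(profile, k_range = 2:8, seed = 1L, n_init = 25) {
  profile <- as.matrix(profile)
  k_range <- k_range[k_range >= 2 & k_range < nrow(profile)]
  D <- as.matrix(dist(profile))
  purrr::map_dfr(k_range, function(k) {
    cl <- kmeans_patterns(profile, k = k, seed = seed, n_init = n_init)$pattern
    sil <- vapply(seq_len(nrow(profile)), function(r) {
      own <- cl == cl[r]; own[r] <- FALSE
      a <- if (any(own)) mean(D[r, own]) else 0
      bs <- vapply(setdiff(unique(cl), cl[r]),
                   function(g) mean(D[r, cl == g]), numeric(1))
      if (length(bs) == 0) return(0)
      b <- min(bs)
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1))
    tibble::tibble(k = k, mean_silhouette = mean(sil))
  })
}

#' Full pattern summary of a selected connection set
#'
#' Convenience wrapper producing the region/network weights, important
#' regions, network degree, within/between counts and the k-means pattern
#' assignment in one object.
#'
#' @param cs [connection_set()].
#' @param profile connections x subjects matrix aligned with `cs` rows
#'   (typically the transposed selected feature columns).
#' @param k number of patterns.
#' @param seed RNG seed.
#' @param n_init k-means restarts.
#' @param mode weight aggregation mode for [region_weights()].
#' @return object of class `pattern_summary`.
#' @export
pattern_summary <- function(cs, profile, k = 3, seed = 1L, n_init = 100,
                            mode = "absolute") {
  rw <- region_weights(cs, mode = mode)
  nw <- network_weights(rw)
  imp <- important_regions(rw)
  nd <- network_degree(cs)
  wb <- within_between_counts(cs)
  pat <- kmeans_patterns(profile, k = k, seed = seed, n_init = n_init)
  per_pattern <- dplyr::bind_cols(cs[, c("name", "network_i", "network_j")],
                                  pattern = pat$pattern) |>
    dplyr::group_by(.data$pattern) |>
    dplyr::summarise(
      n_connections = dplyr::n(),
      n_within = sum(.data$network_i == .data$network_j),
      n_between = sum(.data$network_i != .data$network_j),
      .groups = "drop"
    )
  structure(
    list(region_weight = rw, network_weight = nw, important_regions = imp,
         nd = nd, within_between = wb, pattern_labels = pat,
         per_pattern = per_pattern, k = k, mode = mode),
    class = "pattern_summary"
  )
}

#' @export
print.pattern_summary <- function(x, ...) {
  cat("Pattern summary of", nrow(x$pattern_labels), "selected connections\n")
  cat("network degree:", paste(sprintf("%s=%d", x$nd$network, x$nd$nd), collapse = " "), "\n")
  cat("important regions (2-SD rule):",
      if (nrow(x$important_regions)) paste(x$important_regions$roi, collapse = ", ")
      else "(none)", "\n")
  cat("pattern sizes:", paste(x$per_pattern$n_connections, collapse = "/"), "\n")
  invisible(x)
}

#' Network-degree and pattern plots
#'
#' @param object `pattern_summary`.
#' @param ... unused.
#' @return ggplot object: network degree per network, faceted by pattern
#'   plus the overall set.
#' @export
autoplot.pattern_summary <- function(object, ...) {
  df <- object$nd |> dplyr::mutate(panel = "all connections")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$network, levels = FC_NETWORKS),
                                   y = .data$nd)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "network degree",
                  title = "Between-network degree of the selected connections")
}

#' Region-importance bar chart
#'
#' Contributing regions ranked by classification weight, with the 2-SD
#' important regions highlighted.
#'
#' @param summary `pattern_summary`.
#' @param top_n number of regions to show (default 20).
#' @return ggplot object.
#' @export
plot_region_importance <- function(summary, top_n = 20) {
  rw <- summary$region_weight |>
    dplyr::filter(.data$contributing) |>
    dplyr::arrange(dplyr::desc(.data$weight)) |>
    head(top_n) |>
    dplyr::mutate(important = .data$roi %in% summary$important_regions$roi)
  ggplot2::ggplot(rw, ggplot2::aes(x = stats::reorder(.data$roi, .data$weight),
                                   y = .data$weight, fill = .data$important)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "purple", `FALSE` = "grey60")) +
    ggplot2::labs(x = NULL, y = "region classification weight",
                  fill = "> mean + 2 SD")
}
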