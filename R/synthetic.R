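# Synthetic connectome datasets with the statistical structure the analysis
# assumes: a six-network atlas, Fisher-z FC features with network-block
# latent structure, a sparse set of group-discriminative connections at a
# controlled effect size, clinical scales linearly linked to designated
# connections, and (optionally) ROI time series whose derived FC reproduces
# the same structure. Everything is deterministic given one master seed,
# with named per-stage substreams.

# Six-network ROI counts of the 160-ROI functional atlas.
ATLAS_160_SIZES <- c(DMN = 34, FPN = 21, CON = 32, SMN = 33, ON = 22, CN = 18)

#' Synthetic-dataset configuration
#'
#' Defaults encode the reference conditions the pipeline is designed around: 48
#' patients vs 50 controls, a 160-ROI six-network atlas (12,720
#' connections), 170 retained timepoints (180 volumes minus 10 discarded),
#' 125 discriminative connections, and clinical scales matching the
#' instrument-typical group means/SDs.
#'
#' @param seed master seed; all stages draw from named substreams of it.
#' @param n_patients,n_controls group sizes (defaults 48 / 50).
#' @param R number of ROIs (default 160).
#' @param network_sizes named integer vector over DMN, FPN, CON, SMN, ON,
#'   CN summing to `R`; by default the 160-ROI counts, rescaled
#'   proportionally for other `R`.
#' @param T_timepoints retained timepoints per subject (default 170).
#' @param n_discriminative planted group-discriminative connections
#'   (default 125).
#' @param effect_size Cohen's d of the planted group shift on the Fisher-z
#'   scale (default 1.0).
#' @param latent_sd SD of the per-subject network latent inducing
#'   within-network feature correlation across subjects (default 0.12).
#' @param noise_sd independent feature noise SD on the z scale (default 0.2).
#' @param baseline_within,baseline_between mean z-scale FC of within- and
#'   between-network connections (defaults 0.6 / 0.25).
#' @param n_clinical_linked connections linked to clinical scales
#'   (default 5, one per scale).
#' @param r_clin target population correlation between a linked connection
#'   and its scale (default 0.5).
#' @param round_scales integer-round and clip clinical scales into their
#'   plausible ranges (default TRUE).
#' @param ts_lambda network-latent mixing weight in the time-series path
#'   (default 0.4).
#' @param ts_mixing shared-source mixing weight on planted connections for
#'   patients in the time-series path (default 0.9; controls get 0).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, n_patients = 48, n_controls = 50,
                             R = 160, network_sizes = NULL,
                             T_timepoints = 170,
                             n_discriminative = 125, effect_size = 1.0,
                             latent_sd = 0.12, noise_sd = 0.2,
                             baseline_within = 0.6, baseline_between = 0.25,
                             n_clinical_linked = 5, r_clin = 0.5,
                             round_scales = TRUE,
                             ts_lambda = 0.4, ts_mixing = 0.9) {
  if (is.null(network_sizes)) network_sizes <- scale_network_sizes(R)
  stopifnot(sum(network_sizes) == R, all(network_sizes >= 1),
            identical(sort(names(network_sizes)), sort(FC_NETWORKS)))
  p <- R * (R - 1) / 2
  if (n_discriminative > p) abort("n_discriminative exceeds the number of connections")
  stopifnot(effect_size >= 0, abs(r_clin) < 1, noise_sd > 0, latent_sd >= 0,
            n_clinical_linked <= n_discriminative)
  structure(
    list(seed = as.integer(seed), n_patients = as.integer(n_patients),
         n_controls = as.integer(n_controls), R = as.integer(R),
         network_sizes = network_sizes[FC_NETWORKS],
         T_timepoints = as.integer(T_timepoints),
         n_discriminative = as.integer(n_discriminative),
         effect_size = effect_size, latent_sd = latent_sd,
         noise_sd = noise_sd, baseline_within = baseline_within,
         baseline_between = baseline_between,
         n_clinical_linked = as.integer(n_clinical_linked),
         r_clin = r_clin, round_scales = isTRUE(round_scales),
         ts_lambda = ts_lambda, ts_mixing = ts_mixing),
    class = "synthetic_config"
  )
}

# Largest-remainder rescaling of the 160-ROI network counts to R ROIs.
scale_network_sizes <- function(R) {
  if (R == 160) return(ATLAS_160_SIZES)
  raw <- ATLAS_160_SIZES / 160 * R
  base <- pmax(floor(raw), 1)
  left <- R - sum(base)
  if (left > 0) {
    ord <- order(raw - floor(raw), decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  } else if (left < 0) {
    ord <- order(base, decreasing = TRUE)
    k <- 1
    while (left < 0) {
      if (base[ord[k]] > 1) { base[ord[k]] <- base[ord[k]] - 1; left <- left + 1 }
      k <- if (k == length(base)) 1 else k + 1
    }
  }
  stats::setNames(as.integer(base), names(ATLAS_160_SIZES))
}

#' Generate a synthetic six-network ROI atlas
#'
#' ROIs are assigned to networks in contiguous blocks and given synthetic
#' MNI coordinates drawn within plausible brain-bounding ranges.
#'
#' @param R number of ROIs.
#' @param network_sizes named counts per network summing to `R`.
#' @param seed RNG seed.
#' @return validated atlas tibble (`roi_id` 0-based, `name`, `network`,
#'   `x`, `y`, `z`).
#' @export
generate_atlas <- function(R = 160, network_sizes = scale_network_sizes(R),
                           seed = 1L) {
  if (sum(network_sizes) != R) abort("network sizes must sum to R")
  network <- rep(names(network_sizes), times = network_sizes)
  name <- unlist(lapply(names(network_sizes), function(N) {
    sprintf("%s_%02d", N, seq_len(network_sizes[[N]]))
  }))
  coords <- withr::with_seed(seed, {
    cbind(x = runif(R, -70, 70), y = runif(R, -100, 75), z = runif(R, -45, 80))
  })
  atlas <- tibble::tibble(
    roi_id = seq_len(R) - 1L, name = name, network = network,
    x = round(coords[, 1]), y = round(coords[, 2]), z = round(coords[, 3])
  )
  validate_atlas(atlas)
  atlas
}

# Per-connection marginal SD implied by the generative model.
connection_sd <- function(same_network, latent_sd, noise_sd) {
  sqrt(ifelse(same_network, 4, 2) * latent_sd^2 + noise_sd^2)
}

#' Generate Fisher-z FC features with planted group effects
#'
#' Each subject's z-scale connection vector is `baseline + g_i + g_j +
#' group shift + noise`, where `g` is a per-subject, per-network latent
#' (inducing higher cross-subject correlation of same-network-block
#' features), and the planted connections are shifted by
#' `effect_size * SD_c` for patients so the planted Cohen's d equals
#' `effect_size` by construction.
#'
#' @param atlas atlas tibble.
#' @param cfg [synthetic_config()].
#' @return list with `feature_table` and `truth` (tibbles of planted
#'   discriminative and clinical-linked connections).
#' @export
generate_fc_features <- function(atlas, cfg) {
  validate_atlas(atlas)
  R <- nrow(atlas)
  conn <- connection_index(R, roi_names = atlas$name)
  p <- nrow(conn)
  n <- cfg$n_patients + cfg$n_controls
  same_net <- atlas$network[conn$i] == atlas$network[conn$j]
  mu <- ifelse(same_net, cfg$baseline_within, cfg$baseline_between)
  sd_c <- connection_sd(same_net, cfg$latent_sd, cfg$noise_sd)

  withr::with_seed(sub_seed(cfg$seed, "features"), {
    planted <- sort(sample.int(p, cfg$n_discriminative))
    net_of <- match(atlas$network, FC_NETWORKS)
    G <- matrix(rnorm(n * length(FC_NETWORKS), sd = cfg$latent_sd),
                n, length(FC_NETWORKS))
    latent <- G[, net_of[conn$i]] + G[, net_of[conn$j]]
    noise <- matrix(rnorm(n * p, sd = cfg$noise_sd), n, p)
    X <- matrix(mu, n, p, byrow = TRUE) + latent + noise
    is_patient <- c(rep(TRUE, cfg$n_patients), rep(FALSE, cfg$n_controls))
    shift <- cfg$effect_size * sd_c[planted]
    X[is_patient, planted] <- X[is_patient, planted] +
      matrix(shift, sum(is_patient), length(planted), byrow = TRUE)
  })

  colnames(X) <- conn$name
  ids <- c(sprintf("ASD_%03d", seq_len(cfg$n_patients)),
           sprintf("TDC_%03d", seq_len(cfg$n_controls)))
  labels <- c(rep(1L, cfg$n_patients), rep(-1L, cfg$n_controls))
  ft <- new_feature_table(X, ids, labels, connections = conn)

  linked_pos <- planted[seq_len(cfg$n_clinical_linked)]
  link_of <- if (length(linked_pos) > 0) {
    conn$name[linked_pos[(seq_along(CLINICAL_SCALES) - 1L) %%
                           length(linked_pos) + 1L]]
  } else {
    rep(NA_character_, length(CLINICAL_SCALES))   # noise-only scales
  }
  truth <- list(
    discriminative = conn[planted, , drop = FALSE],
    clinical_linked = tibble::tibble(scale = CLINICAL_SCALES,
                                     connection = link_of)
  )
  list(feature_table = ft, truth = truth)
}

# Published group means/SDs and plausible ranges of the five scales.
SCALE_PARAMS <- tibble::tribble(
  ~scale,               ~mean, ~sd,  ~min, ~max,
  "ADI_R_social",       19.85, 5.10,  0,   30,
  "ADI_R_verbal",       15.34, 3.84,  0,   26,
  "ADOS_total",         11.71, 4.28,  0,   24,
  "ADOS_communication",  3.56, 1.64,  0,   10,
  "ADOS_social",         8.15, 2.97,  0,   14
)

#' Generate clinical scales linked to planted connections
#'
#' Each scale is `r_clin * z_c + sqrt(1 - r_clin^2) * noise` (on the
#' standardized scale of its designated linked connection `c`), mapped to
#' an instrument-typical group mean/SD and, by default, integer-rounded and clipped
#' into the plausible instrument range. The population correlation between
#' the linked connection and the unrounded scale is exactly `r_clin`.
#'
#' @param feature_table feature table (patients are the `label == 1` rows).
#' @param truth truth list from [generate_fc_features()].
#' @param cfg [synthetic_config()].
#' @return clinical tibble (`subject_id` + five scale columns), patients
#'   only.
#' @export
generate_clinical <- function(feature_table, truth, cfg) {
  pat <- dplyr::filter(feature_table, .data$label == 1L)
  if (nrow(pat) == 0) abort("no patients in the feature table")
  out <- tibble::tibble(subject_id = pat$subject_id)
  withr::with_seed(sub_seed(cfg$seed, "clinical"), {
    for (k in seq_len(nrow(SCALE_PARAMS))) {
      sc <- SCALE_PARAMS$scale[k]
      link <- truth$clinical_linked$connection[truth$clinical_linked$scale == sc]
      raw <- if (length(link) == 1 && !is.na(link)) {
        z <- as.numeric(scale(pat[[link]]))
        cfg$r_clin * z + sqrt(1 - cfg$r_clin^2) * rnorm(nrow(pat))
      } else {
        rnorm(nrow(pat))   # no linked connection: pure noise scale
      }
      val <- SCALE_PARAMS$mean[k] + SCALE_PARAMS$sd[k] * raw
      if (cfg$round_scales) {
        val <- pmin(pmax(round(val), SCALE_PARAMS$min[k]), SCALE_PARAMS$max[k])
      }
      out[[sc]] <- val
    }
  })
  out
}

#' Generate ROI time series reproducing the planted FC structure
#'
#' Each ROI signal is a mix of an autocorrelated network latent (elevating
#' within-network FC), shared white-noise sources targeted at the planted
#' connections (mixed in for patients only, elevating those correlations in
#' the patient group), and independent white noise. Running
#' [compute_fc_matrix()] + [fisher_z()] on the output reproduces the
#' elevated within-network FC and the planted group differences in
#' expectation.
#'
#' @param atlas atlas tibble.
#' @param cfg [synthetic_config()]; `T_timepoints` must be >= 30.
#' @param truth optional truth list to reuse (so the time-series path plants
#'   the same connections as the feature path); when NULL the planted set is
#'   drawn from the features substream, making the two paths consistent.
#' @return list with `time_series` (named list of T x R matrices),
#'   `labels` tibble, and `truth`.
#' @export
generate_time_series <- function(atlas, cfg, truth = NULL) {
  validate_atlas(atlas)
  if (cfg$T_timepoints < 30) abort("need at least 30 timepoints")
  R <- nrow(atlas)
  conn <- connection_index(R, roi_names = atlas$name)
  if (is.null(truth)) {
    planted <- withr::with_seed(sub_seed(cfg$seed, "features"),
                                sort(sample.int(nrow(conn), cfg$n_discriminative)))
    truth <- list(discriminative = conn[planted, , drop = FALSE])
  }
  planted_ij <- truth$discriminative
  n <- cfg$n_patients + cfg$n_controls
  ids <- c(sprintf("ASD_%03d", seq_len(cfg$n_patients)),
           sprintf("TDC_%03d", seq_len(cfg$n_controls)))
  is_patient <- c(rep(TRUE, cfg$n_patients), rep(FALSE, cfg$n_controls))
  net_of <- match(atlas$network, FC_NETWORKS)
  Tn <- cfg$T_timepoints
  phi <- 0.3   # AR(1) coefficient of the network latents

  ts_list <- withr::with_seed(sub_seed(cfg$seed, "timeseries"), {
    lapply(seq_len(n), function(s) {
      L <- vapply(seq_along(FC_NETWORKS), function(N) {
        as.numeric(stats::arima.sim(list(ar = phi), Tn, sd = sqrt(1 - phi^2)))
      }, numeric(Tn))
      x <- cfg$ts_lambda * L[, net_of, drop = FALSE] +
        matrix(rnorm(Tn * R), Tn, R)
      a <- if (is_patient[s]) cfg$ts_mixing else 0
      if (a > 0) {
        for (k in seq_len(nrow(planted_ij))) {
          S <- rnorm(Tn)
          x[, planted_ij$i[k]] <- x[, planted_ij$i[k]] + a * S
          x[, planted_ij$j[k]] <- x[, planted_ij$j[k]] + a * S
        }
      }
      colnames(x) <- atlas$name
      x
    })
  })
  names(ts_list) <- ids
  list(
    time_series = ts_list,
    labels = tibble::tibble(subject_id = ids,
                            label = ifelse(is_patient, 1L, -1L)),
    truth = truth
  )
}

#' Generate a complete synthetic dataset
#'
#' @param cfg [synthetic_config()].
#' @param time_series also generate the (slower) per-subject time-series
#'   path (default FALSE; the feature-level path is the primary one).
#' @return object of class `fc_synthetic`: `atlas`, `feature_table`,
#'   `clinical`, `truth`, `config`, and optionally `time_series`.
#' @export
generate_dataset <- function(cfg = synthetic_config(), time_series = FALSE) {
  atlas <- generate_atlas(cfg$R, cfg$network_sizes, seed = sub_seed(cfg$seed, "atlas"))
  feat <- generate_fc_features(atlas, cfg)
  clinical <- generate_clinical(feat$feature_table, feat$truth, cfg)
  out <- list(atlas = atlas, feature_table = feat$feature_table,
              clinical = clinical, truth = feat$truth, config = cfg)
  if (isTRUE(time_series)) {
    out$time_series <- generate_time_series(atlas, cfg, truth = feat$truth)
  }
  structure(out, class = "fc_synthetic")
}

#' @export
print.fc_synthetic <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Synthetic connectome dataset: %d patients + %d controls, %d ROIs (%d connections)\n",
    cfg$n_patients, cfg$n_controls, cfg$R, cfg$R * (cfg$R - 1) / 2
  ))
  cat(sprintf("  %d planted discriminative connections at d = %.2f; %d clinical-linked (r = %.2f)\n",
              cfg$n_discriminative, cfg$effect_size,
              cfg$n_clinical_linked, cfg$r_clin))
  invisible(x)
}
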