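test_that("generated atlases have the requested shape", {
  atlas <- generate_atlas(160)
  expect_equal(nrow(atlas), 160)
  expect_equal(sort(unique(atlas$network)), sort(c("DMN", "FPN", "CON", "SMN", "ON", "CN")))
  counts <- table(atlas$network)
  expect_equal(as.integer(counts[c("DMN", "FPN", "CON", "SMN", "ON", "CN")]),
               c(34, 21, 32, 33, 22, 18))
  small <- generate_atlas(12, setNames(rep(2L, 6), c("DMN", "FPN", "CON", "SMN", "ON", "CN")))
  expect_equal(nrow(small), 12)
  expect_error(generate_atlas(12, setNames(c(2L, 2L, 2L, 2L, 2L, 1L),
                                           c("DMN", "FPN", "CON", "SMN", "ON", "CN"))),
               "sum to R")
})

test_that("feature generation is deterministic and plants the stated effect size", {
  cfg <- planted_config(61, n_patients = 100, n_controls = 100, R = 15,
                        n_discriminative = 10, effect_size = 1.5,
                        n_clinical_linked = 3)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(tibble::as_tibble(d1$feature_table), tibble::as_tibble(d2$feature_table))
  expect_identical(d1$clinical, d2$clinical)
  X <- borutafc:::ft_feature_matrix(d1$feature_table)
  y <- d1$feature_table$label
  planted <- d1$truth$discriminative$name
  # empirical standardized group difference near d = 1.5 on planted columns
  dvals <- vapply(planted, function(cn) {
    (mean(X[y == 1, cn]) - mean(X[y == -1, cn])) / sd(X[, cn][y == -1])
  }, numeric(1))
  se <- sqrt(1 / 100 + 1 / 100)
  expect_true(all(abs(dvals - 1.5) < 2.5 * se + 0.25))
  expect_lt(abs(mean(dvals) - 1.5), 0.15)
})

test_that("null generation produces null t statistics on would-be planted columns", {
  # latent_sd = 0 makes features independent, so the mean |t| concentrates
  cfg <- synthetic_config(seed = 62, n_patients = 50, n_controls = 50, R = 15,
                          n_discriminative = 0, effect_size = 0,
                          n_clinical_linked = 0, latent_sd = 0)
  ds <- generate_dataset(cfg)
  X <- borutafc:::ft_feature_matrix(ds$feature_table)
  y <- ds$feature_table$label
  tvals <- apply(X, 2L, function(col) t.test(col[y == 1], col[y == -1])$statistic)
  # mean |t| under the null is near E|t| ~ sqrt(2/pi)
  expect_lt(abs(mean(abs(tvals)) - sqrt(2 / pi)), 0.2)
  expect_lt(mean(abs(tvals) > 2), 0.12)
})

test_that("within-network features correlate more strongly across subjects", {
  cfg <- planted_config(63, n_patients = 60, n_controls = 60, R = 12,
                        n_discriminative = 0, effect_size = 0, n_clinical_linked = 0,
                        latent_sd = 0.15)
  ds <- generate_dataset(cfg)
  X <- borutafc:::ft_feature_matrix(ds$feature_table)
  conn <- attr(ds$feature_table, "connections")
  nets <- cbind(ds$atlas$network[conn$i], ds$atlas$network[conn$j])
  # connection pairs sharing a network latent co-vary across subjects;
  # pairs touching disjoint networks do not
  C <- cor(X)
  share <- outer(seq_len(nrow(conn)), seq_len(nrow(conn)), Vectorize(function(a, b) {
    length(intersect(nets[a, ], nets[b, ])) > 0
  }))
  ut <- upper.tri(C)
  expect_gt(mean(C[ut & share]), mean(C[ut & !share]) + 0.05)
})

test_that("clinical scales hit the target correlation without rounding", {
  hits <- 0
  for (s in 1:10) {
    cfg <- planted_config(100 + s, n_patients = 48, n_controls = 10, R = 10,
                          n_discriminative = 5, n_clinical_linked = 5,
                          r_clin = 0.9, round_scales = FALSE)
    ds <- generate_dataset(cfg)
    link <- ds$truth$clinical_linked
    r <- cor(ds$feature_table[[link$connection[link$scale == "ADOS_total"]]][ds$feature_table$label == 1],
             ds$clinical$ADOS_total)
    hits <- hits + (abs(r - 0.9) < 0.1)
  }
  expect_gte(hits, 9)
})

test_that("null clinical link gives small empirical correlations", {
  cfg <- planted_config(71, n_patients = 48, n_controls = 10, R = 10,
                        n_discriminative = 5, n_clinical_linked = 5,
                        r_clin = 0, round_scales = FALSE)
  ds <- generate_dataset(cfg)
  link <- ds$truth$clinical_linked
  rs <- vapply(seq_len(nrow(link)), function(k) {
    cor(ds$feature_table[[link$connection[k]]][ds$feature_table$label == 1],
        ds$clinical[[link$scale[k]]])
  }, numeric(1))
  expect_true(mean(abs(rs) < 2 / sqrt(48)) >= 0.8)
})

test_that("time series reproduce elevated FC for shared latents and null otherwise", {
  # mixing zero everywhere: mean off-diagonal r near 0
  cfg0 <- synthetic_config(seed = 81, n_patients = 25, n_controls = 25, R = 8,
                           T_timepoints = 170, n_discriminative = 0,
                           n_clinical_linked = 0, ts_lambda = 0, ts_mixing = 0)
  ts0 <- generate_time_series(generate_atlas(8, seed = 1), cfg0)
  rbar <- mean(vapply(ts0$time_series, function(ts) {
    m <- compute_fc_matrix(ts); mean(m[upper.tri(m)])
  }, numeric(1)))
  expect_lt(abs(rbar), 0.05)
  # planted mixing raises r monotonically for patients
  atlas <- generate_atlas(8, seed = 1)
  r_at <- function(a) {
    cfg <- synthetic_config(seed = 82, n_patients = 30, n_controls = 2, R = 8,
                            T_timepoints = 170, n_discriminative = 3,
                            n_clinical_linked = 0, ts_lambda = 0, ts_mixing = a)
    sim <- generate_time_series(atlas, cfg)
    planted <- sim$truth$discriminative
    pat <- sim$time_series[sim$labels$label == 1]
    mean(vapply(pat, function(ts) {
      m <- compute_fc_matrix(ts)
      mean(m[cbind(planted$i, planted$j)])
    }, numeric(1)))
  }
  r_small <- r_at(0.4); r_big <- r_at(1.2)
  expect_gt(r_small, 0.05)
  expect_gt(r_big, r_small)
  expect_gt(r_big, 0.5)
  # determinism
  cfg <- synthetic_config(seed = 83, n_patients = 3, n_controls = 3, R = 6,
                          T_timepoints = 40, n_discriminative = 2,
                          n_clinical_linked = 0)
  s1 <- generate_time_series(atlas <- generate_atlas(6, seed = 2), cfg)
  s2 <- generate_time_series(atlas, cfg)
  expect_identical(s1$time_series, s2$time_series)
})

test_that("time-series path and feature path agree on where the signal is", {
  atlas <- generate_atlas(12, seed = 3)
  cfg <- synthetic_config(seed = 84, n_patients = 30, n_controls = 30, R = 12,
                          T_timepoints = 120, n_discriminative = 8,
                          effect_size = 1.5, n_clinical_linked = 0,
                          ts_lambda = 0.2, ts_mixing = 0.9)
  feat <- generate_fc_features(atlas, cfg)
  sim <- generate_time_series(atlas, cfg, truth = feat$truth)
  ft_ts <- assemble_feature_table(sim$time_series, atlas,
                                  setNames(sim$labels$label, sim$labels$subject_id))
  tstat <- function(ft) {
    X <- borutafc:::ft_feature_matrix(ft); y <- ft$label
    apply(X, 2L, function(col) t.test(col[y == 1], col[y == -1])$statistic)
  }
  t_feat <- tstat(feat$feature_table)
  t_ts <- tstat(ft_ts)
  expect_gt(cor(t_feat, t_ts), 0.8)
  planted <- feat$truth$discriminative$name
  expect_gt(min(abs(t_ts[planted])), max(1.5, stats::quantile(abs(t_ts[setdiff(names(t_ts), planted)]), 0.9) - 2))
})
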