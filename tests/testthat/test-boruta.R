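test_that("shadow features are columnwise permutations with fresh draws", {
  set.seed(2)
  A <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("f", 1:6)))
  B <- make_shadow_features(A, seed = 9)
  expect_equal(dim(B), dim(A))
  for (k in seq_len(ncol(A))) {
    expect_equal(sort(B[, k]), sort(A[, k]))      # multiset preserved
    expect_equal(mean(B[, k]), mean(A[, k]))
    expect_equal(sd(B[, k]), sd(A[, k]))
  }
  expect_false(identical(make_shadow_features(A, seed = 1),
                         make_shadow_features(A, seed = 2)))
  expect_error(make_shadow_features(matrix(numeric(0), 0, 0)), "at least 2 rows")
})

test_that("shadow-label correlation matches the permutation-null magnitude", {
  # under the null E|r| ~ sqrt(2 / (pi * n)); check the Monte-Carlo mean
  set.seed(5)
  n <- 60
  x <- rnorm(n)
  labels <- rep(c(1, -1), each = n / 2)
  A <- matrix(x, n, 1)
  rs <- vapply(1:400, function(b) abs(cor(make_shadow_features(A)[, 1], labels)),
               numeric(1))
  expect_equal(mean(rs), sqrt(2 / (pi * n)), tolerance = 0.15)
})

test_that("ensemble importance is a nonnegative unit-sum vector that finds signal", {
  set.seed(3)
  n <- 100
  labels <- rep(c(1, -1), each = n / 2)
  top_hits <- 0
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(rnorm(n * 20), n, 20)
    X[, 7] <- labels + rnorm(n, sd = 0.1)   # near-perfect split
    imp <- ensemble_importance(X, labels, n_trees = 100, seed = s)
    expect_true(all(imp >= 0))
    expect_equal(sum(imp), 1, tolerance = 1e-12)
    top_hits <- top_hits + (which.max(imp) == 7)
  }
  expect_gte(top_hits, 9.5)   # >= 95% of the 10 seeds
  expect_error(ensemble_importance(matrix(rnorm(20), 10, 2), rep(1, 10), 50, 1),
               "both classes")
})

test_that("duplicated informative features share importance", {
  set.seed(8)
  n <- 100
  labels <- rep(c(1, -1), each = n / 2)
  X <- matrix(rnorm(n * 10), n, 10)
  X[, 1] <- labels + rnorm(n, sd = 0.3)
  X[, 2] <- X[, 1]
  imp <- ensemble_importance(X, labels, n_trees = 300, seed = 4)
  expect_gt(imp[1], mean(imp[3:10]))
  expect_gt(imp[2], mean(imp[3:10]))
})

test_that("hit update uses strict comparison against the interpolated percentile", {
  shadows <- as.numeric(1:10)
  # type-7 interpolated 95th percentile of shadows is 9 + 0.55 * 1 = 9.55
  expect_equal(quantile(shadows, 0.95, type = 7, names = FALSE), 9.55)
  imp <- c(c(9.6, 9.5, 20, 1, rep(1, 6)), shadows)
  hits <- update_hits(imp, rep(0L, 10), hit_percentile = 95)
  expect_equal(hits[1:4], c(1L, 0L, 1L, 0L))
  # percentile 100: strictly above the shadow maximum; equality is no hit
  imp100 <- c(c(10, 10.5, 20, 1, rep(1, 6)), shadows)
  hits100 <- update_hits(imp100, rep(0L, 10), hit_percentile = 100)
  expect_equal(hits100[1:3], c(0L, 1L, 1L))
  # all reals at the shadow median: no hits at 95
  imp2 <- c(rep(median(shadows), 10), shadows)
  expect_equal(update_hits(imp2, rep(0L, 10), 95), rep(0L, 10))
  expect_error(update_hits(numeric(0), integer(0)), "no features")
})

test_that("binomial decisions match exact tail sums at the extremes", {
  cfg <- boruta_config(null_hit_prob = 0.5, correction = "none")
  # 20 hits in 20 iterations: upper tail 0.5^20
  expect_equal(binomial_decision(20, 20, cfg), "confirmed")
  expect_equal(binomial_decision(0, 20, cfg), "rejected")
  expect_equal(binomial_decision(10, 20, cfg), "undecided")
  expect_error(binomial_decision(21, 20, cfg), "exceed")
})

test_that("decision is monotone in hits for fixed n_iter", {
  cfg <- boruta_config(null_hit_prob = 0.5, correction = "none")
  for (n in c(10, 17, 25)) {
    dec <- vapply(0:n, function(h) binomial_decision(h, n, cfg, m = 1), character(1))
    conf <- dec == "confirmed"
    # once confirmed, every larger hit count is confirmed
    if (any(conf)) expect_true(all(conf[which(conf)[1]:length(conf)]))
    rej <- dec == "rejected"
    if (any(rej)) expect_true(all(rej[1:max(which(rej))]))
  }
})

test_that("two-step correction is the conjunction of BH and Bonferroni", {
  cfg2 <- boruta_config(correction = "two_step_fdr_bonferroni")
  cfgb <- boruta_config(correction = "bonferroni_only")
  # hit counts over a family of 40 features after 15 iterations
  set.seed(1)
  hits <- c(rep(15L, 3), rbinom(37, 15, 0.3))
  d2 <- binomial_decision(hits, 15, cfg2)
  db <- binomial_decision(hits, 15, cfgb)
  # two-step can never confirm what Bonferroni alone does not
  expect_true(all(which(d2 == "confirmed") %in% which(db == "confirmed")))
  p_up <- pbinom(hits - 1, 15, 0.5, lower.tail = FALSE)
  manual <- (stats::p.adjust(p_up, "BH") <= 0.05) & (p_up <= 0.05 / length(hits))
  expect_equal(d2 == "confirmed", manual)
})

test_that("the selection loop partitions features, is seeded, and respects max_iter", {
  cfg <- planted_config(21, n_patients = 20, n_controls = 20, R = 12,
                        n_discriminative = 5, n_clinical_linked = 2)
  ds <- generate_dataset(cfg)
  bcfg <- quick_boruta(17, n_trees = 60, max_iter = 12)
  r1 <- run_boruta(ds$feature_table, bcfg)
  r2 <- run_boruta(ds$feature_table, bcfg)
  expect_identical(r1$decision, r2$decision)       # bit-identical decisions
  expect_identical(r1$hits, r2$hits)
  expect_setequal(levels(r1$decision), c("confirmed", "rejected", "tentative"))
  expect_equal(length(r1$decision), 66)
  expect_true(all(r1$hits <= r1$n_iter_run))
  expect_true(all(r1$confirmed_features %in% r1$feature_names))
  # one iteration: everything decided or tentative after a single pass
  r3 <- run_boruta(ds$feature_table, quick_boruta(17, n_trees = 60, max_iter = 1))
  expect_equal(r3$n_iter_run, 1L)
  expect_true(all(as.character(r3$decision) %in% c("confirmed", "rejected", "tentative")))
  # degenerate inputs
  const <- matrix_table(matrix(1, 10, 4), rep(c(1L, -1L), 5))
  expect_error(run_boruta(const, bcfg), "degenerate")
  onecls <- matrix_table(matrix(rnorm(40), 10, 4), rep(1L, 10))
  expect_error(run_boruta(onecls, bcfg), "both classes")
})

test_that("select_confirmed restricts the table to selected connections", {
  cfg <- planted_config(31, n_patients = 16, n_controls = 16, R = 10,
                        n_discriminative = 4, n_clinical_linked = 2)
  ds <- generate_dataset(cfg)
  res <- run_boruta(ds$feature_table, quick_boruta(5, n_trees = 80, max_iter = 20))
  sel <- select_confirmed(ds$feature_table, res)
  expect_equal(setdiff(names(sel), c("subject_id", "label")),
               res$confirmed_features)
  selt <- select_confirmed(ds$feature_table, res, include_tentative = TRUE)
  expect_gte(ncol(selt), ncol(sel))
  expect_s3_class(tidy(res), "tbl_df")
  g <- glance(res)
  expect_equal(g$n_confirmed + g$n_rejected + g$n_tentative, g$n_features)
})

test_that("selection result serializes to JSON + CSV", {
  cfg <- planted_config(3, n_patients = 10, n_controls = 10, R = 8,
                        n_discriminative = 3, n_clinical_linked = 1)
  ds <- generate_dataset(cfg)
  res <- run_boruta(ds$feature_table, quick_boruta(2, n_trees = 40, max_iter = 8))
  jf <- withr::local_tempfile(fileext = ".json")
  cf <- withr::local_tempfile(fileext = ".csv")
  write_boruta_result(res, jf, cf)
  back <- jsonlite::read_json(jf)
  expect_equal(back$n_iter_run, res$n_iter_run)
  expect_equal(length(back$decisions), length(res$decision))
  hist <- readr::read_csv(cf, show_col_types = FALSE)
  expect_equal(nrow(hist), res$n_iter_run)
})
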