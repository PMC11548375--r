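test_that("the published measurement grouping reproduces its fold durations", {
  plan <- reference_fold_plan()
  expect_equal(plan$duration_min, c(78, 112, 149, 131, 253))
  meta <- example_cohort()
  sub_by_fold <- lapply(plan$groups, function(g)
    unique(meta$subject_id[match(g, meta$measurement_id)]))
  expect_true(all(table(unlist(sub_by_fold)) == 1))   # subject exclusivity
  expect_setequal(plan$assignment$measurement_id, meta$measurement_id)
})

test_that("epoch inventory sums to the binary task total", {
  inv <- epoch_inventory()
  expect_identical(inv$qs + inv$as, inv$binary_total)
  expect_identical(inv$binary_total, 723L)
})

test_that("pooled folds stratify and partition the epochs", {
  labels <- factor(c(rep("AS", 70), rep("QS", 30)))
  plan <- make_folds(scheme = "pooled_10fold", labels = labels, seed = 3)
  expect_equal(sort(unique(plan$assignment$fold)), 1:10)
  expect_equal(nrow(plan$assignment), 100L)
  per_fold_qs <- tapply(labels[plan$assignment$epoch] == "QS",
                        plan$assignment$fold, sum)
  expect_true(all(per_fold_qs == 3))            # 30 QS over 10 folds exactly
  p2 <- make_folds(scheme = "pooled_10fold", labels = labels, seed = 3)
  expect_identical(plan$assignment, p2$assignment)
})

test_that("measurement-out pairing is subject-exclusive and ratio-balanced", {
  set.seed(1)
  meta <- data.frame(
    measurement_id = c("m1", "m2", "m3", "m4", "m5", "m6"),
    subject_id     = c("s1", "s1", "s2", "s3", "s4", "s5"),
    n_qs = c(5, 9, 10, 30, 8, 12), n_as = c(45, 31, 30, 30, 42, 28))
  plan <- make_folds(meta, "leave_measurement_out_5fold")
  expect_equal(lengths(plan$groups), rep(2L, 3))
  # the two-measurement subject is forced into one fold
  forced <- vapply(plan$groups, function(g) setequal(g, c("m1", "m2")), logical(1))
  expect_true(any(forced))
  expect_setequal(unlist(plan$groups), meta$measurement_id)
  # exhaustive pairing minimizes the QS/AS-ratio range: check optimality
  ratio <- function(g) sum(meta$n_qs[match(g, meta$measurement_id)]) /
    sum(meta$n_as[match(g, meta$measurement_id)])
  got_range <- diff(range(vapply(plan$groups, ratio, numeric(1))))
  other <- list(list(c("m1", "m2"), c("m3", "m4"), c("m5", "m6")),
                list(c("m1", "m2"), c("m3", "m6"), c("m5", "m4")))
  for (alt in other) {
    expect_lte(got_range, diff(range(vapply(alt, ratio, numeric(1)))) + 1e-12)
  }
  expect_error(make_folds(meta[1:5, ], "leave_measurement_out_5fold"), "even")
})

test_that("classification metrics match closed forms", {
  lab <- factor(c(rep("QS", 5), rep("AS", 5)))
  perfect <- c(rep(0.9, 5), rep(0.1, 5))
  m <- classification_metrics(lab, perfect)
  expect_equal(unlist(m[c("accuracy", "balanced_accuracy", "f1", "kappa", "auc_roc")]),
               c(accuracy = 100, balanced_accuracy = 100, f1 = 100,
                 kappa = 100, auc_roc = 100))

  # all-QS predictor on a 25%-QS set
  lab2 <- factor(c(rep("QS", 25), rep("AS", 75)))
  m2 <- classification_metrics(lab2, rep(0.9, 100))
  expect_equal(m2$accuracy, 25)
  expect_equal(m2$balanced_accuracy, 50)
  expect_equal(m2$kappa, 0)

  # fixed confusion TP=40 FN=10 FP=20 TN=130 at matching probabilities
  lab3 <- factor(c(rep("QS", 50), rep("AS", 150)))
  p3 <- c(rep(0.9, 40), rep(0.1, 10), rep(0.9, 20), rep(0.1, 130))
  m3 <- classification_metrics(lab3, p3)
  expect_equal(m3$accuracy, 85)
  po <- 0.85; pe <- (50 * 60 + 150 * 140) / 200^2
  expect_equal(m3$kappa, 100 * (po - pe) / (1 - pe), tolerance = 1e-12)
  expect_equal(m3$f1, 100 * 2 * 40 / (2 * 40 + 20 + 10), tolerance = 1e-12)

  single <- classification_metrics(factor(rep("QS", 10), c("AS", "QS")), runif(10))
  expect_true(is.na(single$auc_roc) && single$single_class)
})

test_that("kappa never exceeds accuracy on a single confusion matrix", {
  set.seed(20)
  for (i in 1:200) {
    cm <- rmultinom(1, 200, runif(4, 0.05, 1))
    lab <- factor(c(rep("QS", cm[1] + cm[2]), rep("AS", cm[3] + cm[4])), c("AS", "QS"))
    p <- c(rep(0.9, cm[1]), rep(0.1, cm[2]), rep(0.9, cm[3]), rep(0.1, cm[4]))
    m <- classification_metrics(lab, p)
    expect_lte(m$kappa, m$accuracy + 1e-9)
  }
})

test_that("vitals agreement statistics match their definitions", {
  x <- c(150, 152, 148, 151)
  same <- vitals_agreement(x, x)
  expect_equal(unlist(same[c("me", "rmse", "loa")]), c(me = 0, rmse = 0, loa = 0))
  off <- vitals_agreement(x + 2, x)
  expect_equal(unlist(off[c("me", "rmse", "loa")]), c(me = 2, rmse = 2, loa = 0))
  set.seed(4)
  a <- rnorm(500, 140, 8); b <- a + rnorm(500, -1, 2)
  got <- vitals_agreement(a, b)
  d <- a - b
  expect_equal(got$me, sum(d) / 500, tolerance = 1e-12)
  expect_equal(got$rmse, sqrt(sum(d^2) / 500), tolerance = 1e-12)
  expect_equal(got$loa, 1.96 * sqrt(sum((d - mean(d))^2) / 499), tolerance = 1e-12)
  expect_equal(got$pearson_r, 100 * cor(a, b), tolerance = 1e-12)
  expect_gte(got$rmse, abs(got$me))
  expect_error(vitals_agreement(1:2, 1:2), "at least 3")
})

test_that("cross-validation reports match an independent refit of each fold", {
  es <- toy_epochs(40, 20, noise = 8, seed = 5)
  plan <- make_folds(scheme = "pooled_10fold", labels = es$label, k = 3, seed = 2)
  spec <- benchmark_spec("XGB", n_rounds = 15L)
  rep1 <- run_cross_validation(es, plan, list(spec), seed = 11)
  expect_equal(nrow(rep1$per_fold), 3L)
  expect_equal(sum(rep1$per_fold$tp + rep1$per_fold$fn +
                     rep1$per_fold$fp + rep1$per_fold$tn), 60)
  # oracle: refit fold 2 by hand with the same seed policy
  f <- 2L
  tr <- nirsleep:::subset_epochs(es, which(plan$assignment$fold != f))
  te <- nirsleep:::subset_epochs(es, which(plan$assignment$fold == f))
  m <- train_benchmark(tr, spec, compute_class_weights(tr$label), seed = 11 + f)
  oracle <- classification_metrics(te$label, predict_proba(m, te))
  got <- rep1$per_fold[rep1$per_fold$fold == f, ]
  expect_equal(got$accuracy, oracle$accuracy)
  expect_equal(got$kappa, oracle$kappa)
  # identical specs give identical reports
  rep2 <- run_cross_validation(es, plan, list(spec), seed = 11)
  expect_identical(rep1$per_fold, rep2$per_fold)
})

test_that("measurement-level plans drive recording-wise held-out folds", {
  sets <- lapply(1:4, function(i) {
    es <- toy_epochs(12, 8, noise = 6, seed = i)
    es$recording_id <- rep(paste0("m", i), 20)
    es$subject_id <- rep(paste0("s", i), 20)
    es
  })
  pooled <- bind_epochs(sets)
  meta <- data.frame(measurement_id = paste0("m", 1:4),
                     subject_id = paste0("s", 1:4),
                     n_qs = rep(8, 4), n_as = rep(12, 4))
  plan <- make_folds(meta, "leave_measurement_out_5fold")
  rep <- run_cross_validation(pooled, plan, list(benchmark_spec("KNN")), seed = 1)
  expect_equal(nrow(rep$per_fold), 2L)           # 4 measurements -> 2 paired folds
  expect_equal(rep$per_fold$tp + rep$per_fold$fn, c(16, 16))
})

test_that("PMA sensitivity analysis behaves at its degenerate settings", {
  sets <- lapply(1:4, function(i) {
    es <- toy_epochs(14, 10, noise = 4, seed = 10 + i)
    es$recording_id <- rep(paste0("m", i), 24)
    es$subject_id <- rep(paste0("s", i), 24)
    es
  })
  pooled <- bind_epochs(sets)
  meta <- data.frame(subject_id = paste0("s", 1:4), pma_weeks = c(30, 33, 36, 39))
  spec <- benchmark_spec("XGB", n_rounds = 10L)
  out1 <- pma_sensitivity(pooled, meta, spec, n_boot = 1L, seed = 5)
  expect_equal(nrow(out1$per_subject), 4L)
  expect_true(all(out1$correlations$metric %in%
                    c("accuracy", "balanced_accuracy", "f1", "kappa")))
  ok <- !out1$correlations$constant
  expect_true(all(abs(out1$correlations$r_pct[ok]) <= 100))
  expect_true(all(out1$correlations$p_value[ok] >= 0 &
                    out1$correlations$p_value[ok] <= 1))
  # n_boot = 1 equals the plain leave-one-subject-out loop
  oracle <- vapply(paste0("s", 1:4), function(s) {
    tr <- nirsleep:::subset_epochs(pooled, which(pooled$subject_id != s))
    te <- nirsleep:::subset_epochs(pooled, which(pooled$subject_id == s))
    m <- train_benchmark(tr, spec, compute_class_weights(tr$label), seed = 5 + 1)
    classification_metrics(te$label, predict_proba(m, te))$accuracy
  }, numeric(1))
  expect_equal(out1$per_subject$accuracy, unname(oracle))
  expect_error(pma_sensitivity(pooled, meta[1:2, ], spec), "at least 3")
})
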