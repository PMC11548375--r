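test_that("inverse-frequency class weights follow N/(2*Nc)", {
  lab <- c(rep("AS", 532), rep("QS", 191))
  w <- compute_class_weights(lab)
  expect_equal(unname(w["QS"] / w["AS"]), 532 / 191, tolerance = 1e-12)
  expect_equal(unname(w["AS"]), 723 / (2 * 532))
  expect_equal(unname(compute_class_weights(c("AS", "QS", "AS", "QS"))), c(1, 1))
  expect_error(compute_class_weights(rep("QS", 10)), "both classes")
})

test_that("benchmark specs carry the tuned hyperparameters", {
  expect_equal(benchmark_spec("RF")$params[c("n_trees", "max_depth", "min_split")],
               list(n_trees = 100L, max_depth = 20L, min_split = 2L))
  expect_equal(benchmark_spec("XGB")$params[c("learning_rate", "max_depth")],
               list(learning_rate = 0.2, max_depth = 3L))
  expect_equal(benchmark_spec("KNN")$params$k, 20L)
  expect_equal(benchmark_spec("NB")$params$kernel_width, 0.05)
  expect_equal(benchmark_spec("SVM")$params[c("cost", "kernel_scale")],
               list(cost = 0.1, kernel_scale = 0.5))
  expect_equal(benchmark_spec("AdaB")$params[c("learning_rate", "min_leaf", "max_splits")],
               list(learning_rate = 0.5, min_leaf = 8L, max_splits = 20L))
  expect_error(benchmark_spec("MLP"), "arg")
})

test_that("every benchmark separates the toy classes perfectly", {
  es <- toy_epochs(30, 30)
  for (id in c("KNN", "NB", "SVM", "RF", "AdaB", "XGB")) {
    m <- train_benchmark(es, benchmark_spec(id), seed = 3)
    p <- predict_proba(m, es)
    expect_true(all(p >= 0 & p <= 1), info = id)
    expect_equal(mean(hard_labels(p) == es$label), 1, info = id)
  }
})

test_that("small-sample ensembles remain usable", {
  es <- toy_epochs(12, 12, noise = 5)
  m <- train_benchmark(es, benchmark_spec("RF", n_trees = 20L), seed = 1)
  expect_true(all(is.finite(predict_proba(m, es))))
  expect_error(train_benchmark(toy_epochs(20, 0), benchmark_spec("RF")),
               "labels must be AS or QS|single class")
})

test_that("prediction is deterministic and the 0.5 tie goes to AS", {
  es <- toy_epochs(25, 25)
  m1 <- train_benchmark(es, benchmark_spec("RF"), seed = 9)
  m2 <- train_benchmark(es, benchmark_spec("RF"), seed = 9)
  expect_identical(predict_proba(m1, es), predict_proba(m2, es))
  p <- predict_proba(m1, es)
  expect_identical(p, predict_proba(m1, es))
  expect_equal(as.character(hard_labels(c(0.5, 0.500001, 0.499999))),
               c("AS", "QS", "AS"))
})

test_that("shape mismatches are rejected at prediction time", {
  es <- toy_epochs(15, 15)
  m <- train_benchmark(es, benchmark_spec("KNN"), seed = 1)
  bad <- es
  bad$x <- es$x[, 1:30, ]
  expect_error(predict_proba(m, structure(bad, class = "epoch_set")), "mismatch")
})

test_that("CART engine reproduces a hand-checkable split", {
  X <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  tr <- nirsleep:::cart_fit(X, y = y, criterion = "gini", max_depth = 3)
  expect_equal(nirsleep:::cart_predict(tr, X), y)
  expect_equal(sum(!tr$leaf), 1L)               # single split suffices
  expect_equal(tr$threshold[!tr$leaf], 6.5)     # midpoint between 3 and 10
})

test_that("CNN backprop matches finite differences", {
  cfg <- cnn_config(conv_filters = c(3L, 4L), dense = 5L, dropout = 0, seed = 2)
  set.seed(2)
  par <- nirsleep:::cnn_init(cfg)
  x <- matrix(rnorm(60 * 8), 60, 8)
  y <- 1; w <- 1.7
  fw <- nirsleep:::cnn_forward(par, x)
  gr <- nirsleep:::cnn_backward(par, x, fw, w * (fw$p - y))
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")) {
    for (i in sample(length(par[[nm]]), min(3, length(par[[nm]])))) {
      eps <- 1e-6
      p2 <- par
      p2[[nm]][i] <- p2[[nm]][i] + eps
      l1 <- nirsleep:::wbce(nirsleep:::cnn_forward(p2, x)$p, y, w)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      l0 <- nirsleep:::wbce(nirsleep:::cnn_forward(p2, x)$p, y, w)
      expect_equal(gr[[nm]][i], (l1 - l0) / (2 * eps), tolerance = 1e-5)
    }
  }
})

test_that("CNN learns separated classes and not shuffled labels", {
  es <- toy_epochs(40, 40, hr_as = 160, hr_qs = 120, noise = 1)
  m <- train_cnn(es, cnn_config(epochs = 30, seed = 1))
  expect_gte(mean(hard_labels(predict_proba(m, es)) == es$label), 0.95)
  expect_lt(utils::tail(m$fit$loss_trace, 1), m$fit$loss_trace[1])

  # permutation control: shuffled labels carry no signal
  es_sh <- es
  set.seed(99)
  es_sh$label <- sample(es$label)
  tr <- nirsleep:::subset_epochs(es_sh, 1:60)
  te <- nirsleep:::subset_epochs(es_sh, 61:80)
  m_sh <- train_cnn(tr, cnn_config(epochs = 15, seed = 1))
  bal <- classification_metrics(te$label, predict_proba(m_sh, te))$balanced_accuracy
  expect_gte(bal, 30); expect_lte(bal, 70)

  expect_error(train_cnn(nirsleep:::subset_epochs(es, 1:40), cnn_config()),
               "both classes|per class")
})

test_that("CNN training is deterministic under a fixed seed", {
  es <- toy_epochs(15, 15, noise = 2)
  m1 <- train_cnn(es, cnn_config(epochs = 5, seed = 7))
  m2 <- train_cnn(es, cnn_config(epochs = 5, seed = 7))
  expect_identical(m1$fit$par, m2$fit$par)
  expect_identical(predict_proba(m1, es), predict_proba(m2, es))
})
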