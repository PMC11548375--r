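## Benchmark classifiers for binary AS-vs-QS classification on flattened
## 8 x 60 feature epochs. QS is the positive class throughout. Each
## classifier carries the published tuned hyperparameters as defaults; the
## MATLAB-style settings (KNN squared-inverse distance weights with
## exhaustive neighbor search, kernel NB width, SVM box constraint and
## kernel scale, AdaBoost leaf/split controls) are mapped one-to-one onto
## this implementation's parameters.

#' Inverse-frequency class weights
#'
#' w_c = N_total / (2 * N_c), computed on training labels only, so the rarer
#' class (QS) receives the larger weight.
#'
#' @param labels factor or character vector with both `AS` and `QS` present.
#' @return named numeric weights `c(AS = ..., QS = ...)`.
#' @export
compute_class_weights <- function(labels) {
  labels <- as.character(labels)
  n <- table(factor(labels, levels = c("AS", "QS")))
  if (any(n == 0)) stopf("both classes must be present in the training set")
  w <- as.numeric(sum(n) / (2 * n))
  names(w) <- names(n)
  w
}

#' Benchmark classifier specification
#'
#' @param id one of `KNN`, `NB`, `SVM`, `RF`, `AdaB`, `XGB`.
#' @param ... hyperparameter overrides of the tuned defaults:
#'   KNN `k = 20` (squared-inverse distance weights, exhaustive search);
#'   NB `kernel_width = 0.05` (normal kernel, on standardized features);
#'   SVM `cost = 0.1`, `kernel_scale = 0.5` (linear kernel);
#'   RF `n_trees = 100`, `max_depth = 20`, `min_split = 2`;
#'   AdaB `learning_rate = 0.5`, `min_leaf = 8`, `max_splits = 20`,
#'   `n_rounds = 50`;
#'   XGB `learning_rate = 0.2`, `max_depth = 3`, `n_rounds = 100`,
#'   `lambda = 1`.
#' @return object of class `benchmark_spec`.
#' @export
benchmark_spec <- function(id = c("KNN", "NB", "SVM", "RF", "AdaB", "XGB"), ...) {
  id <- match.arg(id)
  defaults <- switch(id,
    KNN  = list(k = 20L),
    NB   = list(kernel_width = 0.05),
    SVM  = list(cost = 0.1, kernel_scale = 0.5),
    RF   = list(n_trees = 100L, max_depth = 20L, min_split = 2L, min_leaf = 1L),
    AdaB = list(learning_rate = 0.5, min_leaf = 8L, max_splits = 20L, n_rounds = 50L),
    XGB  = list(learning_rate = 0.2, max_depth = 3L, n_rounds = 100L, lambda = 1)
  )
  params <- utils::modifyList(defaults, list(...))
  structure(list(id = id, params = params), class = "benchmark_spec")
}

## Flatten 8 x 60 x N to N x 480 (column-major within each epoch: all eight
## modalities at second 1, then second 2, ...).
flatten_epochs <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  t(apply(es$x, 3L, as.vector))
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- matrixStats::colSds(X)
  sd[sd < 1e-8] <- 1
  list(mu = mu, sd = sd)
}

standardize_apply <- function(X, sc) sweep(sweep(X, 2L, sc$mu), 2L, sc$sd, `/`)

#' Train a benchmark classifier
#'
#' Flattens each 8 x 60 epoch to a 480-vector, standardizes with
#' training-fold statistics, and fits the named classifier with sample
#' weights from the inverse-frequency class weights.
#'
#' @param epochs training [epoch_set()].
#' @param spec a [benchmark_spec()].
#' @param weights class weights; defaults to [compute_class_weights()] of
#'   the training labels.
#' @param seed RNG seed for the stochastic learners (RF bootstrap, feature
#'   subsampling).
#' @return object of class `nirsleep_model`.
#' @export
train_benchmark <- function(epochs, spec, weights = NULL, seed = 1L) {
  stopifnot(inherits(spec, "benchmark_spec"))
  X <- flatten_epochs(epochs)
  y <- as.integer(epochs$label == "QS")
  if (length(unique(y)) < 2L) stopf("training set contains a single class")
  if (is.null(weights)) weights <- compute_class_weights(epochs$label)
  sw <- unname(weights[as.character(epochs$label)])
  sc <- standardize_fit(X)
  Z <- standardize_apply(X, sc)
  p <- spec$params
  fit <- with_seed(seed, switch(spec$id,
    KNN  = list(Z = Z, y = y, sw = sw, k = p$k),
    NB   = nb_fit(Z, y, sw, p$kernel_width),
    SVM  = svm_fit(Z, y, sw, p$cost, p$kernel_scale),
    RF   = rf_fit(Z, y, sw, p),
    AdaB = adaboost_fit(Z, y, sw, p),
    XGB  = xgb_fit(Z, y, sw, p)
  ))
  structure(list(kind = spec$id, spec = spec, fit = fit, scale = sc,
                 class_weights = weights, seed = seed),
            class = c(paste0("nirsleep_", tolower(spec$id)), "nirsleep_model"))
}

#' Predict QS probabilities
#'
#' @param model a trained `nirsleep_model` (benchmark or CNN).
#' @param epochs an [epoch_set()] with the training feature shape.
#' @return numeric vector of probabilities of QS in `[0, 1]`. Hard labels
#'   use threshold 0.5 with ties (exactly 0.5) assigned to the negative
#'   class AS.
#' @export
predict_proba <- function(model, epochs) UseMethod("predict_proba")

#' Convert QS probabilities to hard labels
#'
#' @param prob probabilities of QS.
#' @return factor with levels AS/QS; `prob > 0.5` maps to QS.
#' @export
hard_labels <- function(prob) {
  factor(ifelse(prob > 0.5, "QS", "AS"), levels = c("AS", "QS"))
}

check_shape <- function(model, epochs) {
  X <- flatten_epochs(epochs)
  if (ncol(X) != length(model$scale$mu)) {
    stopf("feature shape mismatch: model expects %d features, got %d",
          length(model$scale$mu), ncol(X))
  }
  standardize_apply(X, model$scale)
}

## ---- KNN: squared-inverse distance weights, exhaustive search -----------

#' @export
predict_proba.nirsleep_knn <- function(model, epochs) {
  Z <- check_shape(model, epochs)
  f <- model$fit
  cw <- model$class_weights
  ## exhaustive squared euclidean distances test x train
  d2 <- outer(rowSums(Z^2), rep(1, nrow(f$Z))) - 2 * Z %*% t(f$Z) +
    outer(rep(1, nrow(Z)), rowSums(f$Z^2))
  d2[d2 < 0] <- 0
  vapply(seq_len(nrow(Z)), function(i) {
    dd <- d2[i, ]
    nn <- order(dd)[seq_len(min(f$k, length(dd)))]
    if (any(dd[nn] == 0)) {                 # exact matches dominate
      nn <- nn[dd[nn] == 0]
      wv <- cw[ifelse(f$y[nn] == 1L, "QS", "AS")]
    } else {
      wv <- (1 / dd[nn]) * cw[ifelse(f$y[nn] == 1L, "QS", "AS")]
    }
    sum(wv[f$y[nn] == 1L]) / sum(wv)
  }, numeric(1))
}

## ---- Kernel Naive Bayes --------------------------------------------------

nb_fit <- function(Z, y, sw, width) {
  list(Z0 = Z[y == 0L, , drop = FALSE], Z1 = Z[y == 1L, , drop = FALSE],
       w0 = sw[y == 0L], w1 = sw[y == 1L], width = width,
       logprior = log(c(sum(sw[y == 0L]), sum(sw[y == 1L])) / sum(sw)))
}

nb_class_loglik <- function(Zt, Ztr, wtr, h) {
  n_t <- nrow(Zt)
  L <- numeric(n_t)
  wn <- wtr / sum(wtr)
  for (f in seq_len(ncol(Zt))) {
    D <- outer(Zt[, f], Ztr[, f], `-`)
    dens <- drop(exp(-D^2 / (2 * h^2)) %*% wn) / (sqrt(2 * pi) * h)
    L <- L + log(pmax(dens, 1e-300))
  }
  L
}

#' @export
predict_proba.nirsleep_nb <- function(model, epochs) {
  Z <- check_shape(model, epochs)
  f <- model$fit
  l0 <- nb_class_loglik(Z, f$Z0, f$w0, f$width) + f$logprior[1L]
  l1 <- nb_class_loglik(Z, f$Z1, f$w1, f$width) + f$logprior[2L]
  1 / (1 + exp(pmin(pmax(l0 - l1, -700), 700)))
}

## ---- Linear SVM (dual QP) ------------------------------------------------

svm_fit <- function(Z, y, sw, cost, kernel_scale) {
  Zs <- Z / kernel_scale
  ys <- ifelse(y == 1L, 1, -1)
  n <- nrow(Zs)
  K <- tcrossprod(Zs)
  D <- (ys %o% ys) * K
  diag(D) <- diag(D) + 1e-6 * mean(diag(K))
  Ci <- cost * sw
  sol <- quadprog::solve.QP(
    Dmat = D, dvec = rep(1, n),
    Amat = cbind(ys, diag(n), -diag(n)),
    bvec = c(0, rep(0, n), -Ci), meq = 1L)
  alpha <- pmin(pmax(sol$solution, 0), Ci)
  wvec <- drop(t(Zs) %*% (alpha * ys))
  on_margin <- which(alpha > 1e-6 * max(Ci) & alpha < Ci - 1e-6 * max(Ci))
  if (!length(on_margin)) on_margin <- which(alpha > 1e-8)
  b <- mean(ys[on_margin] - drop(Zs[on_margin, , drop = FALSE] %*% wvec))
  list(w = wvec, b = b, kernel_scale = kernel_scale)
}

#' @export
predict_proba.nirsleep_svm <- function(model, epochs) {
  Z <- check_shape(model, epochs)
  f <- model$fit
  dec <- drop((Z / f$kernel_scale) %*% f$w) + f$b
  1 / (1 + exp(-pmin(pmax(dec, -700), 700)))   # logistic link on the margin
}

## ---- Random forest -------------------------------------------------------

rf_fit <- function(Z, y, sw, p) {
  n <- nrow(Z)
  mtry <- max(1L, floor(sqrt(ncol(Z))))
  trees <- vector("list", p$n_trees)
  for (b in seq_len(p$n_trees)) {
    idx <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- cart_fit(Z[idx, , drop = FALSE], y = y[idx], w = sw[idx],
                           criterion = "gini", max_depth = p$max_depth,
                           min_split = p$min_split, min_leaf = p$min_leaf,
                           mtry = mtry)
  }
  list(trees = trees)
}

#' @export
predict_proba.nirsleep_rf <- function(model, epochs) {
  Z <- check_shape(model, epochs)
  preds <- vapply(model$fit$trees, function(tr) cart_predict(tr, Z), numeric(nrow(Z)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
  rowMeans(preds)
}

## ---- AdaBoost (discrete, shrinkage) --------------------------------------

adaboost_fit <- function(Z, y, sw, p) {
  n <- nrow(Z)
  d <- sw / sum(sw)
  trees <- list(); alphas <- numeric(0)
  for (m in seq_len(p$n_rounds)) {
    tr <- cart_fit(Z, y = y, w = d, criterion = "gini",
                   max_depth = 1000L, min_split = 2L * p$min_leaf,
                   min_leaf = p$min_leaf, max_splits = p$max_splits)
    pred <- as.integer(cart_predict(tr, Z) > 0.5)
    err <- sum(d[pred != y])
    if (err <= 0) { trees <- c(trees, list(tr)); alphas <- c(alphas, 10); break }
    if (err >= 0.5) break
    a <- p$learning_rate * log((1 - err) / err)
    trees <- c(trees, list(tr)); alphas <- c(alphas, a)
    d <- d * exp(a * (pred != y))
    d <- d / sum(d)
  }
  if (!length(trees)) {             # no useful weak learner: constant model
    trees <- list(cart_fit(Z, y = y, w = d, criterion = "gini", max_depth = 0L))
    alphas <- 1
  }
  list(trees = trees, alphas = alphas)
}

#' @export
predict_proba.nirsleep_adab <- function(model, epochs) {
  Z <- check_shape(model, epochs)
  f <- model$fit
  score <- numeric(nrow(Z))
  for (m in seq_along(f$trees)) {
    pm <- ifelse(cart_predict(f$trees[[m]], Z) > 0.5, 1, -1)
    score <- score + f$alphas[m] * pm
  }
  1 / (1 + exp(-pmin(pmax(score, -700), 700)))
}

## ---- Gradient-boosted trees (Newton boosting, logistic loss) -------------

xgb_fit <- function(Z, y, sw, p) {
  n <- nrow(Z)
  F <- numeric(n)
  trees <- vector("list", p$n_rounds)
  for (m in seq_len(p$n_rounds)) {
    prob <- 1 / (1 + exp(-F))
    g <- sw * (prob - y)
    h <- pmax(sw * prob * (1 - prob), 1e-12)
    tr <- cart_fit(Z, g = g, h = h, criterion = "newton",
                   max_depth = p$max_depth, min_split = 2L, min_leaf = 1L,
                   lambda = p$lambda)
    trees[[m]] <- tr
    F <- F + p$learning_rate * cart_predict(tr, Z)
  }
  list(trees = trees, learning_rate = p$learning_rate)
}

#' @export
predict_proba.nirsleep_xgb <- function(model, epochs) {
  Z <- check_shape(model, epochs)
  f <- model$fit
  F <- numeric(nrow(Z))
  for (tr in f$trees) F <- F + f$learning_rate * cart_predict(tr, Z)
  1 / (1 + exp(-pmin(pmax(F, -700), 700)))
}

#' @export
print.nirsleep_model <- function(x, ...) {
  cat(sprintf("<nirsleep_model:%s> trained, class weights AS=%.3f QS=%.3f\n",
              x$kind, x$class_weights[["AS"]], x$class_weights[["QS"]]))
  invisible(x)
}
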