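## Cross-validation orchestration, classification metrics, vitals agreement
## statistics, and the postmenstrual-age sensitivity analysis. All metrics
## are reported as percentages; QS is the positive class.

#' Build a cross-validation fold plan
#'
#' Pooled scheme: epoch-level stratified k-fold. Measurement-out scheme:
#' partitions measurements into folds of exactly two, keeping every subject
#' in one fold, minimizing the spread of per-fold QS/AS ratios by exhaustive
#' enumeration of pairings (feasible up to 12 measurements) with a greedy
#' fallback. Subject-out scheme: one fold per subject.
#'
#' @param meta data.frame with one row per measurement: `measurement_id`,
#'   `subject_id`, and (for the measurement-out scheme) `n_qs`, `n_as`
#'   epoch counts. Ignored for the pooled scheme.
#' @param scheme one of `pooled_10fold`, `leave_measurement_out_5fold`,
#'   `leave_one_subject_out`.
#' @param labels epoch labels (required for the pooled scheme).
#' @param k number of folds for the pooled scheme.
#' @param seed RNG seed for the stratified shuffle.
#' @return object of class `fold_plan` with an `assignment` data.frame
#'   (epoch or measurement to fold).
#' @export
make_folds <- function(meta = NULL,
                       scheme = c("pooled_10fold", "leave_measurement_out_5fold",
                                  "leave_one_subject_out"),
                       labels = NULL, k = 10L, seed = 1L) {
  scheme <- match.arg(scheme)
  if (scheme == "pooled_10fold") {
    if (is.null(labels)) stopf("pooled scheme needs epoch labels")
    fold <- integer(length(labels))
    with_seed(seed, for (cls in unique(as.character(labels))) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    })
    return(structure(list(scheme = scheme,
                          assignment = data.frame(epoch = seq_along(labels), fold = fold),
                          k = k, seed = seed), class = "fold_plan"))
  }
  stopifnot(is.data.frame(meta), all(c("measurement_id", "subject_id") %in% names(meta)))
  if (scheme == "leave_one_subject_out") {
    subs <- unique(meta$subject_id)
    assignment <- data.frame(measurement_id = meta$measurement_id,
                             fold = match(meta$subject_id, subs))
    return(structure(list(scheme = scheme, assignment = assignment,
                          groups = split(meta$measurement_id, assignment$fold),
                          seed = seed), class = "fold_plan"))
  }
  ## leave-measurement-out: folds of exactly two measurements
  if (!all(c("n_qs", "n_as") %in% names(meta))) {
    stopf("measurement-out scheme needs n_qs and n_as per measurement")
  }
  if (nrow(meta) %% 2L != 0L) stopf("measurement count must be even for paired folds")
  ## multi-measurement subjects must share a fold; with 2-measurement folds a
  ## subject with two recordings forms a complete fold on its own
  forced <- list(); free <- character(0)
  for (s in unique(meta$subject_id)) {
    ids <- meta$measurement_id[meta$subject_id == s]
    if (length(ids) == 2L) forced[[length(forced) + 1L]] <- ids
    else if (length(ids) == 1L) free <- c(free, ids)
    else stopf("subject %s has %d measurements; cannot pair exclusively", s, length(ids))
  }
  ratio_of <- function(ids) {
    i <- match(ids, meta$measurement_id)
    sum(meta$n_qs[i]) / max(sum(meta$n_as[i]), 1L)
  }
  pairings <- function(ids) {          # all perfect matchings
    if (!length(ids)) return(list(list()))
    a <- ids[1L]
    out <- list()
    for (j in seq_along(ids)[-1L]) {
      rest <- pairings(ids[-c(1L, j)])
      out <- c(out, lapply(rest, function(r) c(list(c(a, ids[j])), r)))
    }
    out
  }
  if (length(free) <= 12L) {
    cand <- pairings(free)
    scores <- vapply(cand, function(pr) {
      r <- c(vapply(forced, ratio_of, numeric(1)), vapply(pr, ratio_of, numeric(1)))
      max(r) - min(r)
    }, numeric(1))
    best <- cand[[which.min(scores)]]
  } else {
    ord <- free[order(vapply(free, function(id) ratio_of(id), numeric(1)))]
    best <- lapply(seq_len(length(ord) / 2L), function(i)
      c(ord[i], ord[length(ord) + 1L - i]))   # greedy high-low pairing
  }
  groups <- c(forced, best)
  structure(list(scheme = scheme,
                 assignment = data.frame(
                   measurement_id = unlist(groups),
                   fold = rep(seq_along(groups), lengths(groups))),
                 groups = groups, seed = seed), class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %s, %d folds\n", x$scheme, max(x$assignment$fold)))
  invisible(x)
}

#' Binary classification metrics (QS positive)
#'
#' Accuracy, balanced accuracy (mean of per-class recalls), F1 on QS,
#' Cohen's kappa and rank-based (Mann-Whitney, midranks for ties) AUC-ROC,
#' all on the 0-100 scale.
#'
#' @param labels true labels (factor/character, AS/QS).
#' @param prob predicted probabilities of QS.
#' @return one-row data.frame `accuracy`, `balanced_accuracy`, `f1`,
#'   `kappa`, `auc_roc` (AUC is `NA` with a `single_class` flag when only
#'   one class is present), plus confusion counts `tp`, `fn`, `fp`, `tn`.
#' @export
classification_metrics <- function(labels, prob) {
  y <- as.character(labels)
  pred <- as.character(hard_labels(prob))
  tp <- sum(y == "QS" & pred == "QS"); fn <- sum(y == "QS" & pred == "AS")
  fp <- sum(y == "AS" & pred == "QS"); tn <- sum(y == "AS" & pred == "AS")
  n <- tp + fn + fp + tn
  acc <- (tp + tn) / n
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  bal <- mean(c(sens, spec), na.rm = TRUE)
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 0
  npos <- tp + fn; nneg <- tn + fp
  auc <- NA_real_
  if (npos > 0 && nneg > 0) {
    r <- rank(prob, ties.method = "average")
    auc <- (sum(r[y == "QS"]) - npos * (npos + 1) / 2) / (npos * nneg)
  }
  data.frame(accuracy = 100 * acc, balanced_accuracy = 100 * bal,
             f1 = 100 * f1, kappa = 100 * kappa, auc_roc = 100 * auc,
             tp = tp, fn = fn, fp = fp, tn = tn,
             single_class = npos == 0 || nneg == 0)
}

#' Vitals agreement statistics
#'
#' Mean error, RMSE, Bland-Altman limit-of-agreement half-width
#' (1.96 * SD of the differences) and Pearson correlation (as %), between an
#' extracted and a reference series on a common grid.
#'
#' @param extracted,reference aligned numeric series (>= 3 finite pairs).
#' @return one-row data.frame `me`, `rmse`, `loa`, `pearson_r`, `n`.
#' @export
vitals_agreement <- function(extracted, reference) {
  ok <- is.finite(extracted) & is.finite(reference)
  x <- extracted[ok]; r <- reference[ok]
  if (length(x) < 3L) stopf("need at least 3 aligned points, got %d", length(x))
  d <- x - r
  pr <- if (stats::sd(x) > 0 && stats::sd(r) > 0) stats::cor(x, r) else NA_real_
  data.frame(me = mean(d), rmse = sqrt(mean(d^2)),
             loa = 1.96 * stats::sd(d), pearson_r = 100 * pr, n = length(x))
}

subset_epochs <- function(es, idx) {
  epoch_set(es$x[, , idx, drop = FALSE], es$label[idx], es$epoch_start_s[idx],
            es$recording_id[idx], es$subject_id[idx])
}

train_spec <- function(epochs, spec, weights, seed) {
  if (inherits(spec, "cnn_config")) {
    cfg <- spec; cfg$seed <- seed
    train_cnn(epochs, cfg, weights)
  } else {
    train_benchmark(epochs, spec, weights, seed)
  }
}

spec_id <- function(spec) if (inherits(spec, "cnn_config")) "CNN" else spec$id

#' Run cross-validation
#'
#' Trains each model spec on k-1 folds (class weights computed from the
#' training folds only) and evaluates the held-out fold. Folds whose
#' evaluation set contains a single class get flagged metrics but the run
#' continues.
#'
#' @param epochs pooled [epoch_set()].
#' @param plan a [make_folds()] plan (epoch-level or measurement-level).
#' @param specs list of model specs ([benchmark_spec()] and/or
#'   [cnn_config()]).
#' @param seed seed for the per-fold model training.
#' @return object of class `eval_report`: `per_fold` (metrics per model and
#'   fold) and `summary` (mean and SD per model).
#' @export
run_cross_validation <- function(epochs, plan, specs, seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(plan, "fold_plan"))
  if (!length(specs)) stopf("no model specs supplied")
  if ("epoch" %in% names(plan$assignment)) {
    if (nrow(plan$assignment) != length(epochs$label)) {
      stopf("plan covers %d epochs but %d supplied", nrow(plan$assignment), length(epochs$label))
    }
    fold_of <- plan$assignment$fold
  } else {
    fold_of <- plan$assignment$fold[match(epochs$recording_id,
                                          plan$assignment$measurement_id)]
    if (anyNA(fold_of)) stopf("plan does not cover all measurements")
  }
  rows <- list()
  for (f in sort(unique(fold_of))) {
    tr <- subset_epochs(epochs, which(fold_of != f))
    te <- subset_epochs(epochs, which(fold_of == f))
    w <- compute_class_weights(tr$label)
    for (spec in specs) {
      model <- train_spec(tr, spec, w, seed + f)
      m <- classification_metrics(te$label, predict_proba(model, te))
      m$fold <- f; m$model <- spec_id(spec)
      rows[[length(rows) + 1L]] <- m
    }
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "balanced_accuracy", "f1", "kappa", "auc_roc")
  summary <- do.call(rbind, lapply(split(per_fold, per_fold$model), function(d) {
    out <- data.frame(model = d$model[1L])
    for (mc in metric_cols) {
      out[[paste0(mc, "_mean")]] <- mean(d[[mc]], na.rm = TRUE)
      out[[paste0(mc, "_sd")]] <- stats::sd(d[[mc]], na.rm = TRUE)
    }
    out
  }))
  rownames(summary) <- NULL
  structure(list(per_fold = per_fold, summary = summary, scheme = plan$scheme),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s\n", x$scheme))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-5s acc %5.1f±%-4.1f balacc %5.1f±%-4.1f f1 %5.1f±%-4.1f kappa %5.1f±%-4.1f auc %5.1f±%-4.1f\n",
                s$model[i], s$accuracy_mean[i], s$accuracy_sd[i],
                s$balanced_accuracy_mean[i], s$balanced_accuracy_sd[i],
                s$f1_mean[i], s$f1_sd[i], s$kappa_mean[i], s$kappa_sd[i],
                s$auc_roc_mean[i], s$auc_roc_sd[i]))
  }
  invisible(x)
}

#' Postmenstrual-age sensitivity analysis
#'
#' Leave-one-subject-out performance per subject with the training set
#' bootstrapped `n_boot` times (resampling epochs with replacement;
#' `n_boot = 1` uses the original training set), followed by Pearson
#' correlation between each metric and PMA.
#'
#' @param epochs pooled [epoch_set()].
#' @param meta data.frame `subject_id`, `pma_weeks` (>= 3 subjects).
#' @param spec model spec to evaluate.
#' @param n_boot bootstrap repetitions of the training set.
#' @param seed RNG seed.
#' @return list with `per_subject` metrics and `correlations`
#'   (`metric`, `r_pct`, `p_value`; `NA` + flag for constant metrics).
#' @export
pma_sensitivity <- function(epochs, meta, spec, n_boot = 10L, seed = 1L) {
  subs <- unique(meta$subject_id)
  if (length(subs) < 3L) stopf("need at least 3 subjects")
  metric_cols <- c("accuracy", "balanced_accuracy", "f1", "kappa")
  rows <- list()
  for (si in seq_along(subs)) {
    s <- subs[si]
    te <- subset_epochs(epochs, which(epochs$subject_id == s))
    tr_all <- subset_epochs(epochs, which(epochs$subject_id != s))
    acc <- matrix(NA_real_, n_boot, length(metric_cols),
                  dimnames = list(NULL, metric_cols))
    for (b in seq_len(n_boot)) {
      tr <- if (n_boot == 1L) tr_all else with_seed(seed + 1000L * si + b, {
        idx <- sample.int(length(tr_all$label), replace = TRUE)
        while (length(unique(tr_all$label[idx])) < 2L) {
          idx <- sample.int(length(tr_all$label), replace = TRUE)
        }
        subset_epochs(tr_all, idx)
      })
      model <- train_spec(tr, spec, compute_class_weights(tr$label), seed + b)
      m <- classification_metrics(te$label, predict_proba(model, te))
      acc[b, ] <- unlist(m[1L, metric_cols])
    }
    out <- as.data.frame(t(colMeans(acc)))
    out$subject_id <- s
    out$pma_weeks <- meta$pma_weeks[match(s, meta$subject_id)]
    rows[[si]] <- out
  }
  per_subject <- do.call(rbind, rows)
  correlations <- do.call(rbind, lapply(metric_cols, function(mc) {
    v <- per_subject[[mc]]
    if (stats::sd(v, na.rm = TRUE) == 0 || all(is.na(v))) {
      data.frame(metric = mc, r_pct = NA_real_, p_value = NA_real_, constant = TRUE)
    } else {
      ct <- stats::cor.test(v, per_subject$pma_weeks)
      data.frame(metric = mc, r_pct = 100 * unname(ct$estimate),
                 p_value = ct$p.value, constant = FALSE)
    }
  }))
  list(per_subject = per_subject, correlations = correlations)
}
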