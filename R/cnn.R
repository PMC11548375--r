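## 1-D convolutional network for 8-modality x 60-sample epochs, implemented
## directly on matrix algebra (im2col convolutions, hand-derived backprop,
## Adam). Architecture: two conv blocks (32 then 64 filters, kernel 5, ReLU,
## max-pool 2), global average pooling, dense 32 + ReLU, dropout, sigmoid
## output. Trained with weighted binary cross-entropy (QS positive class),
## Adam at learning rate 0.001 and batch size 2.

#' CNN configuration
#'
#' @param input_len samples per modality per epoch (60).
#' @param n_channels number of modalities (8).
#' @param conv_filters filters of the two conv blocks.
#' @param kernel kernel length of both conv blocks.
#' @param pool max-pool factor.
#' @param dense width of the dense layer.
#' @param dropout dropout rate on the dense activations during training.
#' @param learning_rate Adam learning rate (0.001).
#' @param batch_size minibatch size (2).
#' @param epochs maximum training epochs.
#' @param patience early-stop patience (epochs without validation
#'   improvement) when a validation split is used.
#' @param val_frac fraction of the training set held out, stratified, for
#'   early stopping; 0 disables early stopping.
#' @param seed RNG seed for initialization, shuffling, dropout and split.
#' @return object of class `cnn_config`.
#' @export
cnn_config <- function(input_len = 60L, n_channels = 8L,
                       conv_filters = c(32L, 64L), kernel = 5L, pool = 2L,
                       dense = 32L, dropout = 0.3,
                       learning_rate = 0.001, batch_size = 2L,
                       epochs = 100L, patience = 15L, val_frac = 0.1,
                       seed = 1L) {
  if (learning_rate <= 0) stopf("learning_rate must be positive")
  if (batch_size < 1L) stopf("batch_size must be at least 1")
  structure(as.list(environment()), class = "cnn_config")
}

im2col_idx <- function(len, k, channels) {
  out_len <- len - k + 1L
  ## rows: output positions; cols: flattened (k x channels) patch entries
  pos <- outer(seq_len(out_len), seq_len(k) - 1L, `+`)          # out_len x k
  idx <- matrix(0L, out_len, k * channels)
  for (c in seq_len(channels)) {
    idx[, (c - 1L) * k + seq_len(k)] <- pos + (c - 1L) * len
  }
  idx
}

cnn_init <- function(cfg) {
  he <- function(nin, nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nin)), nr, nc)
  k <- cfg$kernel; f1 <- cfg$conv_filters[1L]; f2 <- cfg$conv_filters[2L]
  l1 <- cfg$input_len - k + 1L          # 56
  p1 <- l1 %/% cfg$pool                 # 28
  l2 <- p1 - k + 1L                     # 24
  p2 <- l2 %/% cfg$pool                 # 12
  list(W1 = he(k * cfg$n_channels, k * cfg$n_channels, f1), b1 = numeric(f1),
       W2 = he(k * f1, k * f1, f2), b2 = numeric(f2),
       W3 = he(f2, f2, cfg$dense), b3 = numeric(cfg$dense),
       W4 = he(cfg$dense, cfg$dense, 1L), b4 = 0,
       idx1 = im2col_idx(cfg$input_len, k, cfg$n_channels),
       idx2 = im2col_idx(p1, k, f1),
       dims = list(l1 = l1, p1 = p1, l2 = l2, p2 = p2))
}

maxpool2 <- function(A) {
  n <- nrow(A) %/% 2L
  a <- A[2L * seq_len(n) - 1L, , drop = FALSE]
  b <- A[2L * seq_len(n), , drop = FALSE]
  take_a <- a >= b
  list(out = ifelse(take_a, a, b), take_a = take_a)
}

## x: input_len x n_channels matrix (one epoch, time x modality)
cnn_forward <- function(par, x, dropout_mask = NULL) {
  Z1 <- matrix(x[par$idx1], nrow(par$idx1))
  S1 <- sweep(Z1 %*% par$W1, 2L, par$b1, `+`)
  A1 <- pmax(S1, 0)
  P1 <- maxpool2(A1)
  Z2 <- matrix(P1$out[par$idx2], nrow(par$idx2))
  S2 <- sweep(Z2 %*% par$W2, 2L, par$b2, `+`)
  A2 <- pmax(S2, 0)
  P2 <- maxpool2(A2)
  g <- colMeans(P2$out)
  S3 <- drop(g %*% par$W3) + par$b3
  d <- pmax(S3, 0)
  if (!is.null(dropout_mask)) d <- d * dropout_mask
  o <- drop(d %*% par$W4) + par$b4
  p <- 1 / (1 + exp(-min(max(o, -500), 500)))
  list(Z1 = Z1, S1 = S1, P1 = P1, Z2 = Z2, S2 = S2, P2 = P2,
       g = g, S3 = S3, d = d, p = p)
}

## dL/do for weighted BCE with sigmoid: w * (p - y)
cnn_backward <- function(par, x, fw, dout, dropout_mask = NULL) {
  gr <- list()
  gr$b4 <- dout
  gr$W4 <- matrix(fw$d * dout, ncol = 1L)
  dd <- drop(par$W4) * dout
  if (!is.null(dropout_mask)) dd <- dd * dropout_mask
  dS3 <- dd * (fw$S3 > 0)
  gr$W3 <- outer(fw$g, dS3)
  gr$b3 <- dS3
  dg <- drop(par$W3 %*% dS3)
  n2 <- nrow(fw$P2$out)
  dP2 <- matrix(rep(dg / n2, each = n2), n2)
  ## un-pool 2
  dA2 <- matrix(0, 2L * n2, ncol(dP2))
  dA2[2L * seq_len(n2) - 1L, ] <- dP2 * fw$P2$take_a
  dA2[2L * seq_len(n2), ] <- dP2 * !fw$P2$take_a
  dS2 <- dA2 * (fw$S2 > 0)
  gr$W2 <- crossprod(fw$Z2, dS2)
  gr$b2 <- colSums(dS2)
  dZ2 <- dS2 %*% t(par$W2)
  dP1 <- matrix(0, nrow(fw$P1$out), ncol(fw$P1$out))
  acc <- rowsum(as.vector(dZ2), group = as.vector(par$idx2))
  dP1[as.integer(rownames(acc))] <- acc
  n1 <- nrow(fw$P1$out)
  dA1 <- matrix(0, 2L * n1, ncol(dP1))
  dA1[2L * seq_len(n1) - 1L, ] <- dP1 * fw$P1$take_a
  dA1[2L * seq_len(n1), ] <- dP1 * !fw$P1$take_a
  dS1 <- dA1 * (fw$S1 > 0)
  gr$W1 <- crossprod(fw$Z1, dS1)
  gr$b1 <- colSums(dS1)
  gr
}

adam_step <- function(par, gr, st, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(gr)) {
    g <- gr[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    mhat <- st$m[[nm]] / (1 - beta1^t)
    vhat <- st$v[[nm]] / (1 - beta2^t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, st = st)
}

wbce <- function(p, y, w) -w * (y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))

#' Train the 1-D CNN
#'
#' Fits the convolutional classifier with weighted binary cross-entropy,
#' Adam (lr 0.001) and batch size 2. Deterministic given `cfg$seed`.
#' Modalities are standardized with per-modality training statistics.
#'
#' @param epochs training [epoch_set()] (at least 10 epochs per class).
#' @param cfg a [cnn_config()].
#' @param weights class weights (default inverse-frequency on the training
#'   labels).
#' @return `nirsleep_model` with the fitted parameters and the per-epoch
#'   training-loss trace in `fit$loss_trace`.
#' @export
train_cnn <- function(epochs, cfg = cnn_config(), weights = NULL) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(cfg, "cnn_config"))
  y <- as.integer(epochs$label == "QS")
  if (min(table(y)) < 10L) stopf("need at least 10 training epochs per class")
  if (is.null(weights)) weights <- compute_class_weights(epochs$label)
  sw <- unname(weights[as.character(epochs$label)])
  ## per-modality standardization
  mu <- rowMeans(epochs$x, dims = 1L)
  sd <- apply(epochs$x, 1L, stats::sd); sd[sd < 1e-8] <- 1
  xs <- sweep(sweep(epochs$x, 1L, mu), 1L, sd, `/`)
  n <- length(y)
  with_seed(cfg$seed, {
    par <- cnn_init(cfg)
    st <- list(m = lapply(par[1:8], function(z) z * 0),
               v = lapply(par[1:8], function(z) z * 0))
    ## stratified validation split for early stopping
    val_idx <- integer(0)
    if (cfg$val_frac > 0 && n >= 20L) {
      for (cls in 0:1) {
        ic <- which(y == cls)
        nv <- max(1L, floor(length(ic) * cfg$val_frac))
        val_idx <- c(val_idx, sample(ic, nv))
      }
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    eval_loss <- function(p_, idx) {
      mean(vapply(idx, function(i) {
        fw <- cnn_forward(p_, t(xs[, , i]))
        wbce(fw$p, y[i], sw[i])
      }, numeric(1)))
    }
    best <- list(par = par, loss = Inf, wait = 0L)
    loss_trace <- numeric(0)
    step <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0
      for (bs in seq(1L, length(ord), by = cfg$batch_size)) {
        batch <- ord[bs:min(bs + cfg$batch_size - 1L, length(ord))]
        gsum <- NULL
        for (i in batch) {
          mask <- (stats::runif(cfg$dense) >= cfg$dropout) / (1 - cfg$dropout)
          fw <- cnn_forward(par, t(xs[, , i]), mask)
          ep_loss <- ep_loss + wbce(fw$p, y[i], sw[i])
          gr <- cnn_backward(par, t(xs[, , i]), fw, sw[i] * (fw$p - y[i]), mask)
          gsum <- if (is.null(gsum)) gr else mapply(`+`, gsum, gr, SIMPLIFY = FALSE)
        }
        gsum <- lapply(gsum, `/`, length(batch))
        step <- step + 1L
        upd <- adam_step(par[1:8], gsum, st, cfg$learning_rate, step)
        par[names(upd$par)] <- upd$par
        st <- upd$st
      }
      ep_loss <- ep_loss / length(ord)
      if (!is.finite(ep_loss)) {
        stopf("NaN/Inf training loss at epoch %d (lr %g); inspect feature scaling",
              ep, cfg$learning_rate)
      }
      loss_trace <- c(loss_trace, ep_loss)
      if (length(val_idx)) {
        vl <- eval_loss(par, val_idx)
        if (vl < best$loss - 1e-6) {
          best <- list(par = par, loss = vl, wait = 0L)
        } else {
          best$wait <- best$wait + 1L
          if (best$wait >= cfg$patience) break
        }
      }
    }
    if (length(val_idx) && is.finite(best$loss)) par <- best$par
    structure(list(kind = "CNN", spec = cfg, fit = list(par = par, loss_trace = loss_trace),
                   norm = list(mu = mu, sd = sd),
                   scale = list(mu = numeric(8L * 60L), sd = rep(1, 8L * 60L)),
                   class_weights = weights, seed = cfg$seed),
              class = c("nirsleep_cnn", "nirsleep_model"))
  })
}

#' @export
predict_proba.nirsleep_cnn <- function(model, epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (dim(epochs$x)[1L] != length(model$norm$mu)) {
    stopf("feature shape mismatch: model expects %d modalities", length(model$norm$mu))
  }
  xs <- sweep(sweep(epochs$x, 1L, model$norm$mu), 1L, model$norm$sd, `/`)
  vapply(seq_len(dim(xs)[3L]), function(i)
    cnn_forward(model$fit$par, t(xs[, , i]))$p, numeric(1))
}
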