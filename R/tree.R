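## Minimal CART engine shared by the random forest, AdaBoost and the
## Newton-boosted trees. Continuous features only (which is all the feature
## epochs contain). Split search is vectorized per candidate feature via
## prefix sums; trees are stored as flat node tables.
##
## criterion "gini": weighted Gini impurity on binary y in {0,1}; leaf value
##   is the weighted class-1 fraction.
## criterion "newton": second-order gain G^2/(H+lambda) as in gradient
##   boosting; leaf value is -G/(H+lambda).

cart_fit <- function(X, y = NULL, w = NULL, g = NULL, h = NULL,
                     criterion = c("gini", "newton"),
                     max_depth = 20L, min_split = 2L, min_leaf = 1L,
                     mtry = ncol(X), max_splits = Inf, lambda = 1) {
  criterion <- match.arg(criterion)
  n <- nrow(X); p <- ncol(X)
  if (is.null(w)) w <- rep(1, n)
  nodes <- new.env(parent = emptyenv())
  nodes$tab <- list()
  nodes$splits_left <- max_splits

  leaf_value <- function(idx) {
    if (criterion == "gini") {
      sum(w[idx] * y[idx]) / sum(w[idx])
    } else {
      -sum(g[idx]) / (sum(h[idx]) + lambda)
    }
  }

  best_split <- function(idx, feats) {
    best <- NULL
    for (j in feats) {
      xs <- X[idx, j]
      ord <- order(xs)
      xo <- xs[ord]
      k_all <- seq_len(length(idx) - 1L)
      valid <- xo[k_all] < xo[k_all + 1L] &
        k_all >= min_leaf & (length(idx) - k_all) >= min_leaf
      if (!any(valid)) next
      if (criterion == "gini") {
        wo <- w[idx][ord]; yo <- y[idx][ord]
        cw <- cumsum(wo); cwy <- cumsum(wo * yo)
        WT <- cw[length(idx)]; WY <- cwy[length(idx)]
        wl <- cw[k_all]; wy <- cwy[k_all]
        wr <- WT - wl; yr <- WY - wy
        gl <- wl - (wy^2 + (wl - wy)^2) / pmax(wl, 1e-300)
        gr <- wr - (yr^2 + (wr - yr)^2) / pmax(wr, 1e-300)
        parent <- WT - (WY^2 + (WT - WY)^2) / WT
        gain <- parent - (gl + gr)
      } else {
        go <- g[idx][ord]; ho <- h[idx][ord]
        cg <- cumsum(go); ch <- cumsum(ho)
        GT <- cg[length(idx)]; HT <- ch[length(idx)]
        gl2 <- cg[k_all]; hl <- ch[k_all]
        gain <- gl2^2 / (hl + lambda) + (GT - gl2)^2 / (HT - hl + lambda) -
          GT^2 / (HT + lambda)
      }
      gain[!valid] <- -Inf
      k <- which.max(gain)
      if (gain[k] > 1e-10 && (is.null(best) || gain[k] > best$gain)) {
        best <- list(feature = j, threshold = (xo[k] + xo[k + 1L]) / 2,
                     gain = gain[k])
      }
    }
    best
  }

  grow <- function(idx, depth) {
    id <- length(nodes$tab) + 1L
    nodes$tab[[id]] <- list()        # reserve slot
    make_leaf <- function() {
      nodes$tab[[id]] <- list(leaf = TRUE, value = leaf_value(idx),
                              feature = NA_integer_, threshold = NA_real_,
                              left = NA_integer_, right = NA_integer_)
      id
    }
    if (depth >= max_depth || length(idx) < min_split ||
        nodes$splits_left <= 0) return(make_leaf())
    if (criterion == "gini" && length(unique(y[idx])) < 2L) return(make_leaf())
    feats <- if (mtry < p) sample.int(p, mtry) else seq_len(p)
    sp <- best_split(idx, feats)
    if (is.null(sp)) return(make_leaf())
    nodes$splits_left <- nodes$splits_left - 1L
    go_left <- X[idx, sp$feature] <= sp$threshold
    left <- grow(idx[go_left], depth + 1L)
    right <- grow(idx[!go_left], depth + 1L)
    nodes$tab[[id]] <- list(leaf = FALSE, value = NA_real_,
                            feature = sp$feature, threshold = sp$threshold,
                            left = left, right = right)
    id
  }

  grow(seq_len(n), 0L)
  tab <- nodes$tab
  structure(list(
    leaf = vapply(tab, `[[`, logical(1), "leaf"),
    value = vapply(tab, `[[`, numeric(1), "value"),
    feature = vapply(tab, `[[`, integer(1), "feature"),
    threshold = vapply(tab, `[[`, numeric(1), "threshold"),
    left = vapply(tab, `[[`, integer(1), "left"),
    right = vapply(tab, `[[`, integer(1), "right")
  ), class = "cart_tree")
}

cart_predict <- function(tree, X) {
  n <- nrow(X)
  out <- numeric(n)
  for (i in seq_len(n)) {
    node <- 1L
    while (!tree$leaf[node]) {
      node <- if (X[i, tree$feature[node]] <= tree$threshold[node])
        tree$left[node] else tree$right[node]
    }
    out[i] <- tree$value[node]
  }
  out
}
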