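# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Round-trip a double through float32, mirroring how the booster stores
# feature values and split thresholds.
f32 <- function(v) {
  readBin(writeBin(as.numeric(v), raw(), size = 4), "numeric",
          size = 4, n = length(v))
}

# Exhaustive-subset Shapley values for a fitted 3-class booster with few
# features. The value function v(S) follows each tree deterministically on
# features in S and averages children by training cover otherwise; Shapley
# values are then assembled from all 2^p coalitions with the classical
# factorial weights.
brute_force_shap <- function(model, X, nclass = 3L, base = 0.5) {
  booster <- if (inherits(model, "stage_model")) model$booster else model
  trees <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  trees$Split <- f32(trees$Split)
  feats <- colnames(X)
  p <- length(feats)
  skey <- function(S) paste(c(".", sort(S)), collapse = ",")
  tree_expect <- function(tr, x, S) {
    idx <- setNames(seq_len(nrow(tr)), tr$ID)
    rec <- function(id) {
      r <- tr[idx[[id]], ]
      if (r$Feature == "Leaf") return(r$Gain)
      if (r$Feature %in% S) {
        return(rec(if (x[[r$Feature]] < r$Split) r$Yes else r$No))
      }
      cy <- tr$Cover[idx[[r$Yes]]]
      cn <- tr$Cover[idx[[r$No]]]
      (cy * rec(r$Yes) + cn * rec(r$No)) / (cy + cn)
    }
    rec(tr$ID[tr$Node == 0])
  }
  subsets <- lapply(0:(2^p - 1), function(m) feats[bitwAnd(m, 2^(seq_len(p) - 1)) > 0])
  tids_by_class <- lapply(0:(nclass - 1), function(cl) {
    tids <- unique(trees$Tree)
    tids[tids %% nclass == cl]
  })
  out <- array(0, dim = c(nrow(X), nclass, p + 1))
  for (i in seq_len(nrow(X))) {
    x <- as.list(f32(X[i, , drop = TRUE]))
    names(x) <- feats
    for (cl in seq_len(nclass)) {
      v <- vapply(subsets, function(S) {
        base + sum(vapply(tids_by_class[[cl]], function(t) {
          tree_expect(trees[trees$Tree == t, , drop = FALSE], x, S)
        }, numeric(1)))
      }, numeric(1))
      names(v) <- vapply(subsets, skey, character(1))
      for (j in seq_len(p)) {
        g <- feats[j]
        phi <- 0
        for (S in subsets) {
          if (g %in% S) next
          w <- factorial(length(S)) * factorial(p - length(S) - 1) / factorial(p)
          phi <- phi + w * (v[[skey(c(S, g))]] - v[[skey(S)]])
        }
        out[i, cl, j] <- phi
      }
      out[i, cl, p + 1] <- v[[skey(character(0))]]
    }
  }
  out
}

# Literal step-up Benjamini-Hochberg from the definition:
# q_(i) = min_{j >= i} p_(j) * m / j, capped at 1, in input order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Tie-free Spearman rho from the classical rank-difference formula.
spearman_oracle <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}
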