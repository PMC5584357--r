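# Independent oracles used to cross-check the implementation. Each one takes
# a different computational route than the code it checks.

# Squared sample distance correlation via the Szekely V-statistic identity
# dCov^2 = S1 + S2 - 2*S3 computed from raw distance sums; no double
# centering anywhere.
oracle_dcor2 <- function(x, y) {
  n <- length(x)
  a <- abs(outer(x, x, "-"))
  b <- abs(outer(y, y, "-"))
  vstat <- function(a, b) {
    mean(a * b) + mean(a) * mean(b) - 2 * sum(rowSums(a) * rowSums(b)) / n^3
  }
  v <- vstat(a, b)
  vx <- vstat(a, a)
  vy <- vstat(b, b)
  if (vx < 1e-24 || vy < 1e-24) return(0)
  v / sqrt(vx * vy)
}

# Scalar-loop double centering straight from the printed definition.
oracle_double_center <- function(d) {
  n <- nrow(d)
  da <- matrix(0, n, n)
  gm <- sum(d) / n^2
  for (k in seq_len(n)) {
    for (l in seq_len(n)) {
      da[k, l] <- d[k, l] - sum(d[k, ]) / n - sum(d[, l]) / n + gm
    }
  }
  da
}

# Plug-in mutual information via findInterval binning and table().
oracle_mi <- function(x, y, width = 0.1) {
  brk <- seq(0, 1, by = width)
  ix <- findInterval(x, brk, rightmost.closed = TRUE)
  iy <- findInterval(y, brk, rightmost.closed = TRUE)
  ent <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log(p))
  }
  joint <- table(ix, iy)
  ent(rowSums(joint)) + ent(colSums(joint)) - ent(joint)
}

# All-pairs shortest paths by walk enumeration with adjacency-matrix powers.
oracle_bfs_dist <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  diag(d) <- 0
  p <- diag(n)
  for (k in seq_len(n)) {
    p <- (p %*% adj) > 0
    d[p & is.infinite(d)] <- k
  }
  d
}

# Mann-Whitney rank AUC: fraction of concordant (TP, TN) score pairs.
oracle_rank_auc <- function(tp_scores, tn_scores) {
  mean(outer(tp_scores, tn_scores, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Plain trapezoid integration of an ordered (x, y) curve.
oracle_trapz <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1))) / 2
}
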