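# Independent oracles, deliberately implemented differently from the
# package code paths they check.

# Element-by-element Jaccard counting (Eq.-style loop, no vectorisation).
brute_jaccard <- function(u, v) {
  stopifnot(length(u) == length(v))
  c_tt <- 0; c_tf <- 0; c_ft <- 0
  for (k in seq_along(u)) {
    if (u[k] && v[k]) c_tt <- c_tt + 1
    if (u[k] && !v[k]) c_tf <- c_tf + 1
    if (!u[k] && v[k]) c_ft <- c_ft + 1
  }
  denom <- c_tt + c_tf + c_ft
  list(d_j = if (denom == 0) 0 else (c_tf + c_ft) / denom,
       c_tt = c_tt, c_tf = c_tf, c_ft = c_ft)
}

# Horn's quaternion absolute-orientation method: an independent route to
# the optimal rigid superposition (the package uses an SVD Kabsch fit).
quaternion_rmsd <- function(mob, ref) {
  a <- sweep(mob, 2, colMeans(mob))
  b <- sweep(ref, 2, colMeans(ref))
  m <- crossprod(a, b)
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  n <- rbind(
    c(sxx + syy + szz, syz - szy, szx - sxz, sxy - syx),
    c(syz - szy, sxx - syy - szz, sxy + syx, szx + sxz),
    c(szx - sxz, sxy + syx, -sxx + syy - szz, syz + szy),
    c(sxy - syx, szx + sxz, syz + szy, -sxx - syy + szz))
  lambda <- max(eigen(n, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(a^2) + sum(b^2) - 2 * lambda) / nrow(a)
  sqrt(max(0, msd))
}

# ROC AUC as the normalised Mann-Whitney U: count, over every
# (positive, negative) pair, wins + half-ties, under "more favourable
# score wins" with deterministic id tie-breaks already applied upstream.
mann_whitney_auc <- function(rank_of_pos, rank_of_neg) {
  wins <- 0
  for (p in rank_of_pos) {
    for (n in rank_of_neg) {
      if (p < n) wins <- wins + 1
    }
  }
  wins / (length(rank_of_pos) * length(rank_of_neg))
}

# Direct eigendecomposition of the feature covariance matrix.
eigen_pca_oracle <- function(x, k) {
  xc <- sweep(x, 2, colMeans(x))
  ev <- eigen(stats::cov(x), symmetric = TRUE)
  scores <- xc %*% ev$vectors[, seq_len(k), drop = FALSE]
  list(scores = scores,
       explained = ev$values[seq_len(k)] / sum(pmax(ev$values, 0)))
}

random_rigid_transform <- function(xyz, seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  r <- rbind(
    c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[4] * q[1]),
      2 * (q[2] * q[4] + q[3] * q[1])),
    c(2 * (q[2] * q[3] + q[4] * q[1]), 1 - 2 * (q[2]^2 + q[4]^2),
      2 * (q[3] * q[4] - q[2] * q[1])),
    c(2 * (q[2] * q[4] - q[3] * q[1]), 2 * (q[3] * q[4] + q[2] * q[1]),
      1 - 2 * (q[2]^2 + q[3]^2)))
  sweep(xyz %*% t(r), 2, runif(3, -20, 20), "+")
}

all_bool_vectors <- function(len) {
  lapply(seq_len(2^len) - 1,
         function(i) as.logical(bitwAnd(i, 2^(seq_len(len) - 1)) > 0))
}
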