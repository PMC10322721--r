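# Independent oracle implementations, deliberately built on different
# numerical routes than the package (eigen-decompositions instead of svd,
# explicit loops instead of vectorised algebra).

# z-score columns with explicit mean/sd arithmetic
oracle_zscore <- function(X) {
  out <- X
  for (j in seq_len(ncol(X))) {
    mu <- sum(X[, j]) / nrow(X)
    s <- sqrt(sum((X[, j] - mu)^2) / (nrow(X) - 1))
    out[, j] <- (X[, j] - mu) / s
  }
  out
}

# PC scores via eigen-decomposition of the cross-product matrix
oracle_pc_scores <- function(X) {
  e <- eigen(crossprod(X), symmetric = TRUE)
  X %*% e$vectors
}

# leave-one-receptor-out gradient dependence, step by step:
# deflate to PCs n..m, drop receptor column r, project onto the reduced
# matrix's first PC, correlate with the original n-th PC scores
oracle_dependence <- function(X_norm, n, r_idx) {
  e <- eigen(crossprod(X_norm), symmetric = TRUE)
  V <- e$vectors
  Z <- X_norm %*% V                      # = U S, columns in decreasing order
  m <- ncol(X_norm)
  X_defl <- Z[, n:m, drop = FALSE] %*% t(V[, n:m, drop = FALSE])
  Xr <- X_defl[, -r_idx, drop = FALSE]
  er <- eigen(crossprod(Xr), symmetric = TRUE)
  z1 <- Xr %*% er$vectors[, 1]
  rho <- as.numeric(stats::cor(Z[, n], z1))
  1 - rho^2
}

# brute-force vertex-area-weighted parcel mean
oracle_parcel_mean <- function(values, cortex) {
  out <- numeric(length(cortex$area_ids))
  for (a in seq_along(out)) {
    idx <- which(cortex$parcel_labels == a & is.finite(values))
    out[a] <- sum(values[idx] * cortex$vertex_areas[idx]) /
      sum(cortex$vertex_areas[idx])
  }
  out
}

# brute-force fractional overlap by vertex enumeration
oracle_overlap <- function(cortex, src, tgt) {
  su <- sort(unique(src[!is.na(src) & src != 0]))
  tu <- sort(unique(tgt[!is.na(tgt) & tgt != 0]))
  M <- matrix(0, length(su), length(tu))
  for (i in seq_along(su)) {
    for (j in seq_along(tu)) {
      idx <- which(src == su[i] & tgt == tu[j])
      M[i, j] <- sum(cortex$vertex_areas[idx])
    }
    M[i, ] <- M[i, ] / sum(M[i, ])
  }
  M
}
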