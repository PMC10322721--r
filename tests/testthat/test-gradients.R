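test_that("column z-scoring matches direct arithmetic and is affine-invariant", {
  expect_equal(as.numeric(zscore_columns(matrix(1:3, 3, 1,
    dimnames = list(1:3, "r")))), c(-1, 0, 1))
  set.seed(7)
  X <- matrix(rnorm(60), 12, 5, dimnames = list(NULL, paste0("r", 1:5)))
  Z <- zscore_columns(X)
  expect_equal(unname(Z), unname(oracle_zscore(X)), tolerance = 1e-12)
  expect_equal(unname(colMeans(Z)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 2, sd)), rep(1, 5), tolerance = 1e-12)
  # positive affine transform of a column leaves z-scores unchanged
  X2 <- X
  X2[, 3] <- 2.5 * X[, 3] + 7
  expect_equal(zscore_columns(X2), Z, tolerance = 1e-12)
  Xc <- X
  Xc[, 2] <- 1
  expect_error(zscore_columns(Xc), "r2")
})

test_that("the SVD factorisation reconstructs the data and orders variance", {
  set.seed(8)
  X <- oracle_zscore(matrix(rnorm(120), 20, 6,
                            dimnames = list(NULL, paste0("r", 1:6))))
  fit <- receptor_pca(X)
  expect_lt(max(abs(fit$U %*% diag(fit$S) %*% t(fit$V) - X)), 1e-8)
  expect_true(all(diff(fit$S) <= 1e-12))
  expect_equal(unname(crossprod(fit$U)), diag(6), tolerance = 1e-9)
  expect_equal(unname(crossprod(fit$V)), diag(6), tolerance = 1e-9)
  expect_equal(sum(fit$variance_fraction), 1, tolerance = 1e-12)
  # variance fractions match the covariance eigenvalue oracle
  ev <- eigen(crossprod(X), symmetric = TRUE)$values
  expect_equal(fit$variance_fraction, ev / sum(ev), tolerance = 1e-9)
  # scores Z = U S and orthogonal PCs
  expect_equal(fit$scores, fit$U %*% diag(fit$S),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_lt(abs(cor(fit$scores[, 1], fit$scores[, 2])), 1e-9)
  # sign convention: PC1 tracks totals positively
  expect_gt(cor(fit$scores[, 1], rowSums(X)), 0)
})

test_that("PC scores are invariant to global positive rescaling", {
  cx <- tc60()
  tr <- planted_ground_truth(cx, seed = 4)
  m <- generate_receptor_matrix(cx, tr)
  X1 <- zscore_columns(m$per_neuron)
  v <- receptorgradients:::rm_values(m$per_neuron)
  X2 <- zscore_columns(v * 17.3)
  f1 <- receptor_pca(X1)
  f2 <- receptor_pca(X2)
  expect_equal(f1$scores, f2$scores, tolerance = 1e-8)
})

test_that("raw and per-neuron gradients are correlated on the planted fixture", {
  cx <- tc60()
  tr <- planted_ground_truth(cx, seed = 4)
  m <- generate_receptor_matrix(cx, tr)
  f_pn <- receptor_pca(zscore_columns(m$per_neuron))
  f_raw <- receptor_pca(zscore_columns(m$raw))
  expect_gt(abs(cor(f_pn$scores[, 1], f_raw$scores[, 1])), 0.7)
})

test_that("totals, fingerprints and extreme ratios extract what they claim", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3,
              dimnames = list(c("A1", "A2"), c("AMPA", "NMDA", "5HT1A")))
  rmx <- as_receptor_matrix(m, units = "fmol_per_neuron")
  td <- total_density(rmx)
  expect_equal(td$total, rowSums(m), ignore_attr = TRUE)

  fp <- fingerprint(rmx, "A2")
  expect_equal(as.character(fp$receptor), c("AMPA", "NMDA", "5HT1A"))
  expect_equal(fp$density, c(2, 4, 6))
  expect_equal(attr(fp, "total"), 12)
  expect_error(fingerprint(rmx, "A9"), "unknown area")

  # equal totals, different vectors: a receptor swap preserves the total
  m2 <- matrix(c(5, 1, 1, 5, 4, 4), 2, 3,
               dimnames = list(c("B1", "B2"), c("AMPA", "NMDA", "5HT1A")))
  r2 <- as_receptor_matrix(m2, units = "fmol_per_neuron")
  t2 <- total_density(r2)
  expect_equal(unname(t2$total[1]), unname(t2$total[2]))
  expect_false(isTRUE(all.equal(fingerprint(r2, "B1")$density,
                                fingerprint(r2, "B2")$density)))

  er <- extreme_ratio(rmx, "AMPA")
  expect_equal(er$ratio, 2)
  expect_equal(er$max_area, "A2")
  const <- as_receptor_matrix(
    matrix(3, 3, 2, dimnames = list(paste0("A", 1:3), c("AMPA", "NMDA"))),
    units = "fmol_per_neuron")
  expect_equal(extreme_ratio(const, "AMPA")$ratio, 1)
  erref <- extreme_ratio(rmx, "5HT1A", reference_area = "A1")
  expect_equal(erref$ratio, 6 / 5)
  zero <- as_receptor_matrix(
    matrix(c(0, 1), 2, 1, dimnames = list(c("A1", "A2"), "AMPA")),
    units = "fmol_per_neuron")
  expect_error(extreme_ratio(zero, "AMPA"), "not positive")
})

test_that("gradient dependence vanishes for redundant receptors", {
  # rank-1 noiseless data: all z-scored columns share one spatial pattern
  set.seed(9)
  s <- rnorm(10)
  X <- outer(s, runif(4, 0.5, 2)) + outer(rep(1, 10), runif(4, 3, 8))
  X <- cbind(X, X[, 4])  # duplicated receptor
  colnames(X) <- paste0("r", 1:5)
  Xn <- zscore_columns(X)
  dep <- gradient_dependence(receptor_pca(Xn), n = 1, receptor = "r5")
  expect_lt(dep$g, 1e-6)
})

test_that("gradient dependence matches the independent eigen oracle", {
  set.seed(10)
  for (rep in 1:3) {
    X <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, paste0("r", 1:5)))
    Xn <- zscore_columns(X)
    fit <- receptor_pca(Xn)
    for (n in 1:3) {
      dep <- gradient_dependence(fit, n = n)
      for (r in 1:5) {
        expect_lt(abs(dep$g[r] - oracle_dependence(Xn, n, r)), 1e-10)
      }
      expect_true(all(dep$g >= 0 & dep$g <= 1))
    }
  }
})

test_that("the secondary gradient depends on its planted driver", {
  cx <- tc60()
  tr <- planted_ground_truth(cx, noise_sd = 0.2, seed = 7)
  m <- generate_receptor_matrix(cx, tr)
  fit <- receptor_pca(zscore_columns(m$per_neuron))
  dep <- gradient_dependence(fit, n = 2)
  expect_equal(dep$receptor[which.max(dep$g)], tr$dominant_receptor)
  dep1 <- gradient_dependence(fit, n = 1)
  # the shared gradient survives removal of any single receptor
  expect_lt(max(dep1$g), 0.2)
})

test_that("receptor space projects onto the first two gradients", {
  cx <- tc60()
  tr <- planted_ground_truth(cx, noise_sd = 0.1, seed = 12)
  m <- generate_receptor_matrix(cx, tr)
  fit <- receptor_pca(zscore_columns(m$per_neuron))
  rs <- receptor_space(fit)
  expect_equal(rs$PC1, unname(fit$scores[, 1]))
  expect_gte(abs(cor(rs$PC1, tr$gradient_scores[, 1])), 0.95)
  expect_gte(abs(cor(rs$PC2, tr$gradient_scores[, 2])), 0.95)
  expect_lt(abs(cor(rs$PC1, rs$PC2)), 1e-9)
  # rank-1 data: PC2 coordinates collapse to zero
  tr1 <- planted_ground_truth(cx, n_components = 1, noise_sd = 0, seed = 3)
  m1 <- generate_receptor_matrix(cx, tr1)
  rs1 <- receptor_space(receptor_pca(zscore_columns(m1$per_neuron)))
  expect_lt(max(abs(rs1$PC2)), 1e-6 * max(abs(rs1$PC1)))
})

test_that("tidy and glance summarise the fit", {
  set.seed(11)
  X <- oracle_zscore(matrix(rnorm(70), 10, 7,
                            dimnames = list(NULL, paste0("r", 1:7))))
  fit <- receptor_pca(X)
  td <- tidy(fit)
  expect_equal(nrow(td), 7 * 7)
  expect_named(td, c("receptor", "pc", "loading"))
  gl <- glance(fit)
  expect_equal(gl$var_top5, sum(fit$variance_fraction[1:5]))
  expect_equal(gl$n_areas, 10)
})
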