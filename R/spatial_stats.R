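#' Empirical variogram of a parcel map
#'
#' Half the mean squared difference of map values, binned over pairwise
#' distance. Bins are equal-count over the 0-75th percentile of distances
#' (long lags are poorly sampled and dominated by the sphere's geometry).
#'
#' @param values Numeric per-area vector.
#' @param D Distance matrix (mm) matching `values`.
#' @param n_bins Number of lag bins (default 25).
#' @return Tibble `lag` (mean bin distance), `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(values, D, n_bins = 25) {
  stopifnot(length(values) == nrow(D))
  ut <- upper.tri(D)
  d <- D[ut]
  keep <- d <= stats::quantile(d, 0.75)
  d <- d[keep]
  sq <- (outer(values, values, `-`)^2 / 2)[ut][keep]
  bin <- bin_equal_count(d, n_bins)
  tibble::tibble(
    lag = as.numeric(tapply(d, bin, mean)),
    gamma = as.numeric(tapply(sq, bin, mean)),
    n_pairs = as.integer(table(bin))
  )
}

bin_equal_count <- function(d, n_bins) {
  n_bins <- min(n_bins, length(unique(d)))
  pmin(ceiling(rank(d, ties.method = "first") * n_bins / length(d)), n_bins)
}

#' Variogram-matched surrogate maps
#'
#' Generates null maps that preserve a source map's spatial autocorrelation,
#' for correlation inference that does not treat parcels as exchangeable.
#' Each surrogate is built by (1) randomly permuting the source values, (2)
#' smoothing the permutation with a Gaussian distance kernel at each
#' bandwidth in a grid (bandwidth 0 = no smoothing), (3) an affine
#' amplitude adjustment: the candidate is the mix
#' `sqrt(alpha) * smoothed + sqrt(nugget) * white noise`, with the two
#' nonnegative coefficients fit by least squares so the candidate's
#' variogram matches the source's over the lag bins (the nugget reproduces
#' the source's unstructured short-lag variance, the bandwidth its
#' correlation length), then (4) exact rescaling to the source mean and SD.
#' The bandwidth with the smallest variogram residual is kept per
#' surrogate.
#'
#' @param map Per-area values: tibble (`area_id`, `value`) or named vector.
#' @param D Distance matrix from [distance_matrix()].
#' @param n_surr Number of surrogates (>= 100 for inference; default 1000).
#' @param seed Integer seed.
#' @param bandwidths Kernel bandwidth grid in mm; default
#'   `c(0, 2, 5, 10, 15, 20, 30, 45)`.
#' @param n_bins Variogram lag bins (default 25).
#' @return An object of class `surrogate_ensemble`: list with `surrogates`
#'   (`n_surr` x A matrix), `map` (source values), `bandwidth` (chosen per
#'   surrogate), `variogram` (source variogram tibble), `seed`.
#' @export
make_surrogates <- function(map, D, n_surr = 1000, seed = 1,
                            bandwidths = c(0, 2, 5, 10, 15, 20, 30, 45),
                            n_bins = 25) {
  ids <- rownames(D) %||% as.character(seq_len(nrow(D)))
  x <- as_area_vector(map, ids)
  ok <- is.finite(x)
  if (sum(ok) < 10) stop("map must be finite on at least 10 areas")
  x <- x[ok]
  D <- D[ok, ok, drop = FALSE]
  if (stats::sd(x) == 0) stop("constant map: no variance to permute")
  if (n_surr < 100) warning("n_surr < 100: too few surrogates for inference")
  A <- length(x)
  mu <- mean(x); sg <- stats::sd(x)

  # precompute row-normalised smoothing kernels and variogram plumbing
  kernels <- lapply(bandwidths, function(b) {
    if (b <= 0) return(NULL)
    K <- exp(-D^2 / (2 * b^2))
    K / rowSums(K)
  })
  ut_idx <- which(upper.tri(D))
  d_all <- D[ut_idx]
  keep <- d_all <= stats::quantile(d_all, 0.75)
  pair_i <- row(D)[ut_idx][keep]
  pair_j <- col(D)[ut_idx][keep]
  bin <- bin_equal_count(d_all[keep], n_bins)
  nb <- max(bin)
  bin_n <- tabulate(bin, nb)
  vgram_rows <- function(S) {
    # rows of S are maps; returns n x nb matrix of binned semivariances
    sq <- (S[, pair_i, drop = FALSE] - S[, pair_j, drop = FALSE])^2 / 2
    t(rowsum(t(sq), bin)) / rep(bin_n, each = nrow(S))
  }
  gamma_src <- as.numeric(vgram_rows(matrix(x, 1)))

  withr_seed(seed, {
    P <- t(vapply(seq_len(n_surr), function(i) x[sample.int(A)], numeric(A)))
    E <- matrix(stats::rnorm(n_surr * A), n_surr, A)  # nugget noise
    best <- matrix(NA_real_, n_surr, A)
    best_sse <- rep(Inf, n_surr)
    best_bw <- rep(NA_real_, n_surr)
    for (bi in seq_along(bandwidths)) {
      S <- if (is.null(kernels[[bi]])) P else P %*% t(kernels[[bi]])
      S <- (S - rowMeans(S)) / apply(S, 1, stats::sd)  # unit-variance smooth
      G <- vgram_rows(S)
      # per-surrogate nonnegative weighted LS fit:
      # gamma_src ~ alpha * G + nugget, weights 1/gamma_src^2 so the fit
      # (and bandwidth choice below) controls *relative* variogram error
      w <- 1 / gamma_src^2
      Gw <- G * rep(w, each = n_surr)
      sw <- sum(w)
      gx <- rowSums(Gw * rep(gamma_src, each = n_surr))
      gxx <- rowSums(Gw * G)
      gs <- rowSums(Gw)
      sy <- sum(w * gamma_src)
      det <- sw * gxx - gs^2
      alpha <- pmax((sw * gx - gs * sy) / det, 0)
      nug <- pmax((sy - alpha * gs) / sw, 0)
      cand <- S * sqrt(alpha) + E * sqrt(nug)
      # exact source mean/SD
      cand <- (cand - rowMeans(cand)) / apply(cand, 1, stats::sd) * sg + mu
      Gc <- vgram_rows(cand)
      sse <- rowSums((Gc - rep(gamma_src, each = n_surr))^2 *
                       rep(w, each = n_surr))
      upd <- sse < best_sse
      if (any(upd)) {
        best[upd, ] <- cand[upd, , drop = FALSE]
        best_sse[upd] <- sse[upd]
        best_bw[upd] <- bandwidths[bi]
      }
    }
    colnames(best) <- names(x)
    structure(
      list(surrogates = best, map = x, bandwidth = best_bw,
           variogram = tibble::tibble(
             lag = as.numeric(tapply(d_all[keep], bin, mean)),
             gamma = gamma_src),
           seed = seed),
      class = "surrogate_ensemble"
    )
  })
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat("<surrogate_ensemble> ", nrow(x$surrogates), " surrogates over ",
      ncol(x$surrogates), " areas; median bandwidth ",
      stats::median(x$bandwidth), " mm\n", sep = "")
  invisible(x)
}

#' Spatial-autocorrelation-corrected map correlation
#'
#' Pearson correlation between two parcel maps with a two-tailed p-value
#' computed against the surrogate null: the observed |r| is compared with
#' the |correlation| of each surrogate of `map1` with `map2`, and
#' `p = (1 + #(|r_null| >= |r|)) / (1 + n_surr)` (add-one exceedance count,
#' never exactly zero). Pairs with missing values are dropped
#' pairwise; the ensemble must cover the same areas as `map1`.
#'
#' @param map1,map2 Per-area values (tibble `area_id`,`value` or named
#'   vectors). `map1` must be the map the ensemble was built from.
#' @param ensemble A [make_surrogates()] ensemble for `map1`.
#' @return Tibble `r`, `p_spatial`, `n`, `ci_lo`, `ci_hi` (Fisher-z 95% CI).
#' @export
corrected_correlation <- function(map1, map2, ensemble) {
  stopifnot(inherits(ensemble, "surrogate_ensemble"))
  ids <- colnames(ensemble$surrogates)
  x <- as_area_vector(map1, ids)
  y <- as_area_vector(map2, ids)
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 10) stop("fewer than 10 jointly non-missing areas (n = ",
                         sum(ok), ")")
  if (max(abs(x[ok] - ensemble$map[ok])) > 1e-9) {
    stop("ensemble was not built on map1 (values differ)")
  }
  r <- stats::cor(x[ok], y[ok])
  S <- ensemble$surrogates[, ok, drop = FALSE]
  yc <- y[ok] - mean(y[ok])
  Sc <- S - rowMeans(S)
  r_null <- as.numeric(Sc %*% yc) /
    (sqrt(rowSums(Sc^2)) * sqrt(sum(yc^2)))
  n_surr <- nrow(S)
  p <- (1 + sum(abs(r_null) >= abs(r))) / (1 + n_surr)
  n <- sum(ok)
  zr <- atanh(r); se <- 1 / sqrt(n - 3)
  tibble::tibble(r = r, p_spatial = p, n = n,
                 ci_lo = tanh(zr - 1.96 * se),
                 ci_hi = tanh(zr + 1.96 * se))
}

#' Bonferroni adjustment for a planned family of comparisons
#'
#' `p_adj = min(1, m * p)` with `m` the number of planned comparisons
#' (defaults to the length of `p`; may be larger, never smaller).
#'
#' @param p Numeric p-values in [0, 1].
#' @param m Number of planned comparisons.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (m < length(p)) stop("m must be at least the number of p-values")
  pmin(1, m * p)
}
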