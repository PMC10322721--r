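#' Column z-scoring of a receptor matrix
#'
#' Standardises each receptor column to mean 0, SD 1 (sample SD, n-1
#' denominator) so that high-density receptors do not dominate the principal
#' components. Rows (areas) with any missing value are dropped listwise with
#' a message before scaling; a constant column is an error naming the
#' receptor.
#'
#' @param matrix A `receptor_matrix` tibble or a numeric matrix.
#' @return Numeric matrix `X_norm` with the same dimnames.
#' @export
zscore_columns <- function(matrix) {
  m <- if (inherits(matrix, "receptor_matrix")) rm_values(matrix)
       else as.matrix(matrix)
  bad_row <- !stats::complete.cases(m)
  if (any(bad_row)) {
    message("zscore_columns: dropping ", sum(bad_row),
            " area(s) with missing values")
    m <- m[!bad_row, , drop = FALSE]
  }
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  }
  scale(m, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Principal-component receptor gradients
#'
#' Singular value decomposition of the z-scored area x receptor matrix,
#' `X_norm = U S V^T`. The PC scores — the receptor gradients, one value per
#' area — are `Z = U S`; `V`'s columns are the receptor loadings, and PC k
#' explains a fraction `S_k^2 / sum_j S_j^2` of the variance. All
#' `m = min(A, R)` components are retained. Signs are fixed for
#' reproducibility: PC1 is oriented so its scores correlate positively with
#' total density (row sums of `X_norm` by default), and each later PC so
#' its largest-|loading| receptor loads positively.
#'
#' @param X_norm Z-scored matrix from [zscore_columns()] (a
#'   `receptor_matrix` is z-scored on the fly).
#' @param totals Optional per-area totals used to orient PC1; defaults to
#'   `rowSums(X_norm)`.
#' @return An object of class `receptor_pca`: list with `X_norm`, `U`, `S`
#'   (vector of singular values, non-increasing), `V`, `scores` (`Z = U S`,
#'   areas x m), `loadings` (= `V`), `variance_fraction` (length m).
#'   Supports [tidy()], [glance()] and [ggplot2::autoplot()].
#' @export
receptor_pca <- function(X_norm, totals = NULL) {
  if (inherits(X_norm, "receptor_matrix")) X_norm <- zscore_columns(X_norm)
  X_norm <- as.matrix(X_norm)
  stopifnot(all(is.finite(X_norm)))
  sv <- svd(X_norm)
  m <- length(sv$d)
  if (is.null(totals)) totals <- rowSums(X_norm)
  # sign convention
  flip <- rep(1, m)
  z1 <- sv$u[, 1] * sv$d[1]
  if (stats::sd(totals) > 0 && stats::sd(z1) > 0 &&
      stats::cor(z1, totals) < 0) flip[1] <- -1
  if (m >= 2) {
    for (k in 2:m) {
      j <- which.max(abs(sv$v[, k]))
      if (sv$v[j, k] < 0) flip[k] <- -1
    }
  }
  U <- sweep(sv$u, 2, flip, `*`)
  V <- sweep(sv$v, 2, flip, `*`)
  Z <- U %*% diag(sv$d, m, m)
  pcs <- paste0("PC", seq_len(m))
  dimnames(Z) <- list(rownames(X_norm), pcs)
  dimnames(V) <- list(colnames(X_norm), pcs)
  structure(
    list(X_norm = X_norm, U = U, S = sv$d, V = V,
         scores = Z, loadings = V,
         variance_fraction = sv$d^2 / sum(sv$d^2)),
    class = "receptor_pca"
  )
}

#' @export
print.receptor_pca <- function(x, ...) {
  cat("<receptor_pca> ", nrow(x$scores), " areas x ", nrow(x$V),
      " receptors; variance fractions: ",
      paste(sprintf("%.3f", utils::head(x$variance_fraction, 5)),
            collapse = ", "),
      if (length(x$variance_fraction) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Total receptor density per area
#'
#' Row sums over receptors — with per-neuron units, the total receptor
#' density per neuron, which the first receptor gradient tracks closely.
#'
#' @param matrix A `receptor_matrix` tibble or numeric matrix.
#' @return Tibble with `area_id`, `total`.
#' @export
total_density <- function(matrix) {
  m <- if (inherits(matrix, "receptor_matrix")) rm_values(matrix)
       else as.matrix(matrix)
  tibble::tibble(area_id = rownames(m) %||% as.character(seq_len(nrow(m))),
                 total = unname(rowSums(m)))
}

#' Receptor fingerprint of one cortical area
#'
#' The vector of all receptor densities for a single area in canonical
#' receptor order, plus its total — the quantity conventionally drawn as a
#' polar plot. See [plot_fingerprint()].
#'
#' @param matrix A `receptor_matrix` tibble.
#' @param area_id Area identifier.
#' @return Tibble with `receptor` (ordered factor), `density`; attribute
#'   `total`.
#' @export
fingerprint <- function(matrix, area_id) {
  stopifnot(inherits(matrix, "receptor_matrix"))
  if (!area_id %in% matrix$area_id) stop("unknown area: ", area_id)
  m <- rm_values(matrix)
  ord <- intersect(receptor_names(), colnames(m))
  ord <- c(ord, setdiff(colnames(m), ord))
  v <- m[area_id, ord]
  out <- tibble::tibble(receptor = factor(ord, levels = ord),
                        density = as.numeric(v))
  attr(out, "total") <- sum(v)
  attr(out, "area_id") <- area_id
  out
}

#' Dynamic range of one receptor across areas
#'
#' Ratio of the maximum density of a receptor to its minimum (or to a named
#' reference area), with the areas attaining the extremes. Raw 5-HT2A
#' densities, for instance, have a famously flat range while 5-HT1A spans
#' more than an order of magnitude relative to primary visual cortex.
#'
#' @param matrix A `receptor_matrix` tibble.
#' @param receptor Receptor column name.
#' @param reference_area Optional area id used as the denominator instead of
#'   the minimum.
#' @return Tibble: `receptor`, `ratio`, `max_area`, `min_area` (or
#'   `reference_area`), `max_density`, `denom_density`.
#' @export
extreme_ratio <- function(matrix, receptor, reference_area = NULL) {
  stopifnot(inherits(matrix, "receptor_matrix"))
  m <- rm_values(matrix)
  if (!receptor %in% colnames(m)) stop("unknown receptor: ", receptor)
  v <- m[, receptor]
  imax <- which.max(v)
  if (is.null(reference_area)) {
    imin <- which.min(v)
    denom <- v[imin]; denom_area <- rownames(m)[imin]
  } else {
    if (!reference_area %in% rownames(m)) {
      stop("unknown reference area: ", reference_area)
    }
    denom <- v[reference_area]; denom_area <- reference_area
  }
  if (denom <= 0) stop("denominator density is not positive")
  tibble::tibble(receptor = receptor, ratio = unname(v[imax] / denom),
                 max_area = rownames(m)[imax], min_area = denom_area,
                 max_density = unname(v[imax]),
                 denom_density = unname(denom))
}

#' Leave-one-receptor-out gradient dependence
#'
#' Measures how much the n-th receptor gradient's spatial pattern relies on
#' a single receptor. With `X_norm = U S V^T` and `Z = U S`, the matrix with
#' the first (n-1) PCs removed is `X^(PCn+) = Z_(n+) V_(n+)^T` (dropping the
#' first n-1 columns of `Z` and `V`). Receptor `r`'s column is then deleted
#' — without re-centering or re-scaling — and the data are projected onto
#' the first PC of the reduced matrix, giving scores `Z_1,r-`. The
#' dependence is `g = 1 - rho^2`, where `rho` is the Pearson correlation
#' between `Z_n` and `Z_1,r-`; squaring makes `g` invariant to the
#' arbitrary signs of PCs. `g` is 0 when the gradient survives the removal
#' unchanged and approaches 1 when it collapses.
#'
#' @param fit A [receptor_pca()] object (or an `X_norm` matrix, decomposed
#'   on the fly).
#' @param n PC index (>= 1).
#' @param receptor Receptor (column) to remove; `NULL` computes all.
#' @return Tibble with columns `pc`, `receptor`, `rho`, `g`.
#' @export
gradient_dependence <- function(fit, n = 1, receptor = NULL) {
  if (!inherits(fit, "receptor_pca")) fit <- receptor_pca(fit)
  m <- length(fit$S)
  R <- nrow(fit$V)
  stopifnot(n >= 1, n <= m)
  if (R < 3) stop("need at least 3 receptors")
  receptors <- receptor %||% rownames(fit$V)
  stopifnot(all(receptors %in% rownames(fit$V)))
  keep <- n:m
  X_defl <- fit$scores[, keep, drop = FALSE] %*%
    t(fit$V[, keep, drop = FALSE])
  colnames(X_defl) <- rownames(fit$V)
  Zn <- fit$scores[, n]
  res <- purrr::map_dfr(receptors, function(r) {
    Xr <- X_defl[, setdiff(colnames(X_defl), r), drop = FALSE]
    sv <- svd(Xr, nu = 1, nv = 0)
    if (sv$d[1] < 1e-12) stop("reduced matrix is rank 0 after removing ", r)
    z1 <- sv$u[, 1] * sv$d[1]
    rho <- stats::cor(Zn, z1)
    tibble::tibble(pc = n, receptor = r, rho = rho, g = 1 - rho^2)
  })
  res
}

#' Full gradient-dependence table
#'
#' [gradient_dependence()] for every (PC, receptor) pair up to `max_pc`.
#'
#' @param fit A [receptor_pca()] object.
#' @param max_pc Highest PC index (default 5, capped at m).
#' @return Long tibble `pc`, `receptor`, `rho`, `g`.
#' @export
dependence_table <- function(fit, max_pc = 5) {
  if (!inherits(fit, "receptor_pca")) fit <- receptor_pca(fit)
  max_pc <- min(max_pc, length(fit$S))
  purrr::map_dfr(seq_len(max_pc), function(n) gradient_dependence(fit, n))
}

#' Receptor-space coordinates
#'
#' Projects every area onto the first two PCs — the plane spanned by the
#' principal (total-density) and secondary gradients. Optional group labels
#' are passed through untouched for plotting.
#'
#' @param fit A [receptor_pca()] object with at least 2 components.
#' @param groups Optional per-area labels (named vector or tibble
#'   `area_id`, `group`).
#' @return Tibble `area_id`, `PC1`, `PC2` (+ `group`).
#' @export
receptor_space <- function(fit, groups = NULL) {
  stopifnot(inherits(fit, "receptor_pca"), length(fit$S) >= 2)
  out <- tibble::tibble(
    area_id = rownames(fit$scores) %||%
      as.character(seq_len(nrow(fit$scores))),
    PC1 = unname(fit$scores[, 1]), PC2 = unname(fit$scores[, 2])
  )
  if (!is.null(groups)) {
    if (is.data.frame(groups)) {
      out <- dplyr::left_join(out, groups, by = "area_id")
    } else {
      out$group <- unname(groups[out$area_id])
    }
  }
  out
}

## ---- broom-style methods ------------------------------------------------

#' Tidy a receptor PCA fit
#'
#' `tidy()` returns the loadings in long form (one row per receptor x PC);
#' `glance()` returns a one-row summary with per-PC variance fractions for
#' the first five PCs and the cumulative top-5 fraction.
#'
#' @param x A `receptor_pca` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.receptor_pca <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "receptor") |>
    tidyr::pivot_longer(-"receptor", names_to = "pc",
                        values_to = "loading") |>
    dplyr::mutate(pc = as.integer(sub("^PC", "", .data$pc))) |>
    dplyr::arrange(.data$pc, .data$receptor)
}

#' @rdname tidy.receptor_pca
#' @export
glance.receptor_pca <- function(x, ...) {
  vf <- x$variance_fraction
  k <- min(5, length(vf))
  out <- tibble::as_tibble(as.list(stats::setNames(
    vf[seq_len(k)], paste0("var_pc", seq_len(k)))))
  out$var_top5 <- sum(vf[seq_len(k)])
  out$n_areas <- nrow(x$scores)
  out$n_receptors <- nrow(x$V)
  out
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
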