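#' Per-network summary of a gradient map
#'
#' Pools vertex-level gradient values within each cognitive network and
#' reports the mean alongside the full distribution (for raincloud-style
#' plots). Per-area maps are painted piecewise-constant onto vertices first.
#' The limbic network is excluded by default.
#'
#' @param gradient Per-vertex numeric vector, or per-area map (tibble
#'   `area_id`,`value` or named vector).
#' @param cortex A [generate_toy_cortex()] object.
#' @param exclude Networks to drop (default `"limbic"`).
#' @return List with `summary` (tibble `network`, `mean`, `n_vertices`) and
#'   `distribution` (long tibble `network`, `value`).
#' @export
network_summary <- function(gradient, cortex, exclude = "limbic") {
  v <- if (is.numeric(gradient) && length(gradient) == nrow(cortex$vertices)
           && is.null(names(gradient))) {
    as.numeric(gradient)
  } else {
    paint_vertices(cortex, gradient)
  }
  net <- cortex$network_names[cortex$network_labels]
  keep <- !(net %in% exclude) & is.finite(v)
  dist <- tibble::tibble(network = net[keep], value = v[keep])
  summ <- dist |>
    dplyr::group_by(.data$network) |>
    dplyr::summarise(mean = mean(.data$value),
                     n_vertices = dplyr::n(), .groups = "drop")
  missing_nets <- setdiff(setdiff(cortex$network_names, exclude),
                          summ$network)
  if (length(missing_nets)) {
    message("network_summary: no vertices for ",
            paste(missing_nets, collapse = ", "))
  }
  list(summary = summ, distribution = dist)
}

#' Binarize a functional z-map
#'
#' Strict threshold: vertices with `z > threshold` (default 3.1, the
#' conventional two-tailed p < 0.001 cutoff) form the activation mask. An
#' empty mask is an error — downstream embedding is undefined without
#' supra-threshold vertices.
#'
#' @param map Tibble (`vertex`, `z`) or numeric per-vertex vector.
#' @param threshold Positive z cutoff (default 3.1).
#' @return Integer vector of mask vertex indices.
#' @export
binarize <- function(map, threshold = 3.1) {
  stopifnot(threshold > 0)
  z <- if (is.data.frame(map)) {
    stopifnot(all(c("vertex", "z") %in% names(map)))
    v <- rep(NA_real_, max(map$vertex))
    v[map$vertex] <- map$z
    v
  } else as.numeric(map)
  stopifnot(all(is.finite(z) | is.na(z)))
  mask <- which(z > threshold)
  if (length(mask) == 0) {
    stop("no vertex exceeds z = ", threshold, "; mask is empty")
  }
  mask
}

#' Dice-coefficient embedding of a mask along a gradient
#'
#' Partitions the gradient's vertices into `n_bins` equal-count percentile
#' bins (bin sizes differ by at most one; ties broken by stable vertex
#' order) and computes the Dice coefficient
#' `2 |mask n bin| / (|mask| + |bin|)` of the activation mask with each bin.
#' The scalar embedding position is the Dice-weighted bin centroid
#' `sum(b * Dice_b) / sum(Dice_b)` (set `position = "argmax"` for the
#' modal bin instead).
#'
#' @param mask Integer vertex indices from [binarize()].
#' @param gradient Per-vertex numeric gradient values.
#' @param n_bins Number of percentile bins (default 20).
#' @param position `"centroid"` (default) or `"argmax"`.
#' @return An object of class `dice_embedding`: tibble `bin`, `dice`,
#'   `bin_size`, with attributes `position` and `n_mask`.
#' @export
dice_embedding <- function(mask, gradient, n_bins = 20,
                           position = c("centroid", "argmax")) {
  position <- match.arg(position)
  gradient <- as.numeric(gradient)
  nv <- length(gradient)
  stopifnot(length(mask) >= 1, all(mask >= 1 & mask <= nv))
  if (n_bins > nv) stop("n_bins exceeds the number of vertices")
  if (any(!is.finite(gradient[mask]))) {
    stop("gradient not finite on all masked vertices")
  }
  rk <- rank(gradient, ties.method = "first")
  bin <- pmin(ceiling(rk * n_bins / nv), n_bins)
  bin_size <- tabulate(bin, n_bins)
  in_mask <- logical(nv)
  in_mask[mask] <- TRUE
  inter <- tabulate(bin[in_mask], n_bins)
  dice <- 2 * inter / (length(mask) + bin_size)
  pos <- if (position == "centroid") {
    sum(seq_len(n_bins) * dice) / sum(dice)
  } else {
    which.max(dice)
  }
  out <- tibble::tibble(bin = seq_len(n_bins), dice = dice,
                        bin_size = bin_size)
  attr(out, "position") <- pos
  attr(out, "n_mask") <- length(mask)
  class(out) <- c("dice_embedding", class(out))
  out
}

#' Mean receptor expression within an activation mask
#'
#' The functional receptor fingerprint: for each receptor, the
#' vertex-area-weighted mean of its vertex-level density map over the
#' supra-threshold vertices of a functional map. Vertices without receptor
#' data are excluded (count reported).
#'
#' @param mask Integer vertex indices.
#' @param receptor_maps Vertices x receptors numeric matrix (paint a
#'   `receptor_matrix` with [receptor_vertex_maps()]).
#' @param cortex A [generate_toy_cortex()] object (vertex areas).
#' @return Tibble `receptor`, `density`.
#' @export
functional_fingerprint <- function(mask, receptor_maps, cortex) {
  stopifnot(length(mask) >= 1)
  M <- receptor_maps[mask, , drop = FALSE]
  w <- cortex$vertex_areas[mask]
  ok <- stats::complete.cases(M)
  if (!any(ok)) stop("no masked vertex carries receptor data")
  if (any(!ok)) message("functional_fingerprint: excluding ", sum(!ok),
                        " masked vertices without receptor data")
  dens <- colSums(M[ok, , drop = FALSE] * w[ok]) / sum(w[ok])
  tibble::tibble(receptor = colnames(receptor_maps),
                 density = unname(dens))
}

#' Vertex-level receptor maps from an area x receptor matrix
#'
#' Paints each area's density onto its vertices (piecewise constant), the
#' standard surface rendering of parcel-resolution receptor data.
#'
#' @param matrix A `receptor_matrix` tibble.
#' @param cortex A [generate_toy_cortex()] object.
#' @return Vertices x receptors numeric matrix.
#' @export
receptor_vertex_maps <- function(matrix, cortex) {
  m <- rm_values(matrix)
  idx <- match(cortex$area_ids[cortex$parcel_labels], rownames(m))
  out <- m[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Place functional maps in two-dimensional receptor space
#'
#' Locates each functional activation map in the plane spanned by two
#' receptor gradients: its coordinate along each gradient is the
#' Dice-embedding position, linearly rescaled from bin units (1..n_bins) to
#' that gradient's score range. Homology weights, where supplied, pass
#' through for rendering intensity.
#'
#' @param maps Named list of functional z-maps (tibbles `vertex`, `z`).
#' @param gradient1,gradient2 Per-vertex gradient values.
#' @param threshold Binarization threshold (default 3.1).
#' @param n_bins Percentile bins (default 20).
#' @param homology Optional named numeric weights in [0, 1] per map.
#' @return Tibble `label`, `position1`, `position2` (gradient-score units),
#'   `bin1`, `bin2` (bin units), `homology`.
#' @export
place_in_receptor_space <- function(maps, gradient1, gradient2,
                                    threshold = 3.1, n_bins = 20,
                                    homology = NULL) {
  stopifnot(length(maps) >= 1, !is.null(names(maps)))
  purrr::imap_dfr(maps, function(fm, label) {
    mask <- binarize(fm, threshold)
    e1 <- dice_embedding(mask, gradient1, n_bins)
    e2 <- dice_embedding(mask, gradient2, n_bins)
    b1 <- attr(e1, "position"); b2 <- attr(e2, "position")
    rescale <- function(b, g) {
      min(g) + (b - 1) / (n_bins - 1) * (max(g) - min(g))
    }
    tibble::tibble(
      label = label,
      position1 = rescale(b1, gradient1),
      position2 = rescale(b2, gradient2),
      bin1 = b1, bin2 = b2,
      homology = if (is.null(homology)) NA_real_
                 else unname(homology[label])
    )
  })
}
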