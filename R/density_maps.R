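#' Vertex-area-weighted parcel average of a vertex map
#'
#' Averages a per-vertex scalar within each cortical area, weighting each
#' vertex by its surface area so irregular meshes do not bias the mean.
#' Non-finite vertex values are excluded (their count is reported via a
#' message); an area with no finite vertex is returned as `NA` rather than
#' fabricated.
#'
#' @param vertex_map Numeric vector, one value per mesh vertex, or a tibble
#'   with columns `vertex`, `value` (or `z`).
#' @param cortex A [generate_toy_cortex()] object.
#' @return Tibble with columns `area_id`, `value`, `n_vertices`.
#' @export
parcel_average <- function(vertex_map, cortex) {
  v <- vertex_map_vector(vertex_map, nrow(cortex$vertices))
  w <- cortex$vertex_areas
  lab <- cortex$parcel_labels
  ok <- is.finite(v)
  n_bad <- sum(!ok)
  if (n_bad > 0) message("parcel_average: excluding ", n_bad,
                         " non-finite vertices")
  num <- rowsum((v * w)[ok], lab[ok])
  den <- rowsum(w[ok], lab[ok])
  out <- rep(NA_real_, length(cortex$area_ids))
  idx <- as.integer(rownames(num))
  out[idx] <- num / den
  nv <- tabulate(lab[ok], nbins = length(cortex$area_ids))
  tibble::tibble(area_id = cortex$area_ids, value = out, n_vertices = nv)
}

vertex_map_vector <- function(vertex_map, nv) {
  if (is.data.frame(vertex_map)) {
    val_col <- intersect(c("value", "z"), names(vertex_map))[1]
    stopifnot(!is.na(val_col), "vertex" %in% names(vertex_map))
    v <- rep(NA_real_, nv)
    v[vertex_map$vertex] <- vertex_map[[val_col]]
    v
  } else {
    stopifnot(length(vertex_map) == nv)
    as.numeric(vertex_map)
  }
}

#' Fractional overlap between two labelings of the same mesh
#'
#' For each source label s and target label t, the fraction of s's surface
#' area (vertex-area-weighted) that carries target label t:
#' `overlap(s, t) = area(s intersect t) / area(s)`. Rows over assigned
#' vertices sum to 1; an empty source label yields a flagged all-NA row.
#' Vertices labelled `NA` or 0 in either labelling are excluded from both
#' margins. This row-stochastic matrix is the weight table used to resample
#' maps between parcellations (or from areas onto networks).
#'
#' @param cortex A [generate_toy_cortex()] object (supplies vertex areas).
#' @param source_labels,target_labels Integer (or factor/character) label per
#'   vertex; defaults are the cortex's parcel and network labels.
#' @param source_ids,target_ids Optional id vectors naming the rows/columns.
#' @return An object of class `parcel_overlap`: list with `overlap`
#'   (row-stochastic matrix), `empty_rows` (logical flag per source label).
#' @export
compute_overlap <- function(cortex,
                            source_labels = cortex$parcel_labels,
                            target_labels = cortex$network_labels,
                            source_ids = NULL, target_ids = NULL) {
  nv <- nrow(cortex$vertices)
  stopifnot(length(source_labels) == nv, length(target_labels) == nv)
  s <- as_label_int(source_labels)
  t <- as_label_int(target_labels)
  keep <- !is.na(s$idx) & !is.na(t$idx)
  w <- cortex$vertex_areas[keep]
  si <- s$idx[keep]; ti <- t$idx[keep]
  ns <- length(s$levels); nt <- length(t$levels)
  M <- matrix(0, ns, nt)
  acc <- rowsum(w, (ti - 1L) * ns + si)
  cell <- as.integer(rownames(acc))
  M[cell] <- acc
  rs <- rowSums(M)
  empty <- rs == 0
  M[!empty, ] <- M[!empty, , drop = FALSE] / rs[!empty]
  M[empty, ] <- NA_real_
  rownames(M) <- source_ids %||% s$levels
  colnames(M) <- target_ids %||% t$levels
  structure(list(overlap = M, empty_rows = stats::setNames(empty, rownames(M))),
            class = "parcel_overlap")
}

as_label_int <- function(lab) {
  if (is.numeric(lab)) lab[lab == 0] <- NA
  f <- factor(lab)
  list(idx = as.integer(f), levels = levels(f))
}

#' @export
print.parcel_overlap <- function(x, ...) {
  cat("<parcel_overlap> ", nrow(x$overlap), " source x ",
      ncol(x$overlap), " target labels; ", sum(x$empty_rows),
      " empty source rows\n", sep = "")
  invisible(x)
}

#' Overlap-weighted resampling of a parcel map
#'
#' Carries a per-target-frame scalar map onto the source frame:
#' `out(s) = sum_t overlap(s, t) * map(t)`. Because each row of the overlap
#' matrix is a convex combination, every output value is bounded by the
#' range of the target values it touches. Flagged empty rows propagate as
#' `NA`. The direction is explicit: rows of `overlap` define the output
#' frame.
#'
#' @param source_map Numeric vector named by the overlap matrix's column ids,
#'   or tibble (`area_id`, `value`) in the target frame.
#' @param overlap A [compute_overlap()] object.
#' @return Tibble with `area_id` (source frame) and `value`.
#' @export
overlap_resample <- function(source_map, overlap) {
  stopifnot(inherits(overlap, "parcel_overlap"))
  M <- overlap$overlap
  v <- as_area_vector(source_map, colnames(M))
  if (any(is.na(v))) stop("map missing values for target ids: ",
                          paste(colnames(M)[is.na(v)], collapse = ", "))
  out <- as.numeric(M %*% v)
  out[overlap$empty_rows] <- NA_real_
  tibble::tibble(area_id = rownames(M), value = out)
}

#' Convert raw receptor densities to densities per neuron
#'
#' Raw autoradiography densities are fmol of binding sites per mg of protein.
#' With a neuron-density map (neurons per gram of tissue) and the protein
#' mass fraction of brain tissue (default 0.08), the per-neuron density is
#' `raw * protein_fraction * 1000 / neuron_density` — a per-area constant
#' rescaling (1000 converts mg of protein per gram of tissue). Column
#' z-scoring absorbs the global constant, so downstream PCA gradients do not
#' depend on `protein_fraction`.
#'
#' @param raw A `receptor_matrix` in `fmol_per_mg_protein` units.
#' @param neuron_density Per-area neurons per gram: named vector or tibble
#'   (`area_id`, `value`).
#' @param protein_fraction Protein mass fraction of tissue (default 0.08).
#' @return A `receptor_matrix` in `fmol_per_neuron` units.
#' @export
per_neuron <- function(raw, neuron_density,
                       protein_fraction = .protein_fraction_default) {
  stopifnot(inherits(raw, "receptor_matrix"))
  if (rm_units(raw) != "fmol_per_mg_protein") {
    stop("input must be in fmol_per_mg_protein units")
  }
  m <- rm_values(raw)
  nd <- as_area_vector(neuron_density, rownames(m))
  bad <- !is.finite(nd) | nd <= 0
  if (any(bad)) stop("non-positive or missing neuron density for area(s): ",
                     paste(rownames(m)[bad], collapse = ", "))
  out <- m * protein_fraction * .mg_per_g / nd
  as_receptor_matrix(out, units = "fmol_per_neuron")
}

#' Area x cognitive-network overlap table with limbic exclusion
#'
#' Tabulates, for every cortical area, the fraction of its surface lying in
#' each of the 7 cognitive networks, and flags areas that are
#' majority-limbic (> 0.5 overlap) for exclusion from network summaries —
#' the limbic network is conventionally dropped for lack of usable data.
#'
#' @param cortex A [generate_toy_cortex()] object with network labels.
#' @param limbic Name of the limbic network (default `"limbic"`).
#' @param exclusion_threshold Overlap fraction above which an area is
#'   flagged (default 0.5).
#' @return Tibble: `area_id`, one fraction column per network, and
#'   `excluded` (logical).
#' @export
network_table <- function(cortex, limbic = "limbic",
                          exclusion_threshold = 0.5) {
  ov <- compute_overlap(cortex, cortex$parcel_labels, cortex$network_labels,
                        source_ids = cortex$area_ids,
                        target_ids = cortex$network_names)
  M <- ov$overlap
  out <- tibble::as_tibble(M, rownames = "area_id")
  out$excluded <- unname(M[, limbic] > exclusion_threshold)
  out
}
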