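#' Remove probes without a valid gene identifier
#'
#' Drops probes whose `entrez_valid` flag is unset, the first step of the
#' microarray-to-parcel pipeline.
#'
#' @param set A [generate_sample_set()] object (or real-shaped equivalent).
#' @return The filtered `sample_set`; number removed reported via message.
#' @export
filter_probes_entrez <- function(set) {
  stopifnot(inherits(set, "sample_set"))
  keep <- set$probes$entrez_valid
  if (!any(keep)) stop("all probes lack a valid gene identifier")
  n_drop <- sum(!keep)
  if (n_drop > 0) message("filter_probes_entrez: removing ", n_drop,
                          " probe(s)")
  subset_probes(set, keep)
}

subset_probes <- function(set, keep) {
  set$probes <- set$probes[keep, , drop = FALSE]
  set$intensity <- set$intensity[, keep, drop = FALSE]
  set$calls <- set$calls[, keep, drop = FALSE]
  set
}

subset_samples <- function(set, keep) {
  set$samples <- set$samples[keep, , drop = FALSE]
  set$intensity <- set$intensity[keep, , drop = FALSE]
  set$calls <- set$calls[keep, , drop = FALSE]
  set
}

#' Assign microarray samples to mesh vertices
#'
#' Drops samples farther than `max_dist` from the nearest mesh vertex, then
#' assigns each survivor to its nearest vertex, at most one sample per
#' vertex: processing samples in stable order (donor id, then sample id), a
#' sample whose nearest vertex is taken moves to the nearest unoccupied
#' vertex.
#'
#' @param set A `sample_set`.
#' @param cortex A [generate_toy_cortex()] object in the same coordinate
#'   frame.
#' @param max_dist Drop threshold in mm (default 2).
#' @return Tibble `sample_id`, `donor_id`, `vertex`, `area_id`, `dist`
#'   (mm to the assigned vertex), one row per retained sample; attribute
#'   `n_dropped`.
#' @export
assign_samples <- function(set, cortex, max_dist = 2) {
  stopifnot(inherits(set, "sample_set"), inherits(cortex, "toy_cortex"))
  V <- cortex$vertices
  S <- as.matrix(set$samples[, c("x", "y", "z")])
  ns <- nrow(S)
  if (ns > nrow(V)) stop("more samples (", ns, ") than vertices (",
                         nrow(V), ")")
  # squared distances sample x vertex
  D2 <- outer(rowSums(S^2), rep(1, nrow(V))) +
    outer(rep(1, ns), rowSums(V^2)) - 2 * S %*% t(V)
  D2[D2 < 0] <- 0
  nearest_d <- sqrt(apply(D2, 1, min))
  keep <- nearest_d <= max_dist
  n_dropped <- sum(!keep)
  if (n_dropped > 0) message("assign_samples: dropping ", n_dropped,
                             " sample(s) > ", max_dist, " mm from the mesh")
  ord <- order(set$samples$donor_id, set$samples$sample_id)
  ord <- ord[keep[ord]]
  occupied <- logical(nrow(V))
  vtx <- integer(ns); dist <- numeric(ns)
  for (i in ord) {
    pref <- order(D2[i, ])
    j <- pref[which(!occupied[pref])[1]]
    occupied[j] <- TRUE
    vtx[i] <- j
    dist[i] <- sqrt(D2[i, j])
  }
  out <- tibble::tibble(
    sample_id = set$samples$sample_id[ord],
    donor_id = set$samples$donor_id[ord],
    vertex = vtx[ord],
    area_id = cortex$area_ids[cortex$parcel_labels[vtx[ord]]],
    dist = dist[ord]
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Z-score probe intensities within each sample
#'
#' Standardises each sample's probe vector to mean 0, SD 1 (n-1
#' denominator), removing sample- and donor-level intensity offsets.
#'
#' @param set A `sample_set` with at least 2 probes.
#' @return The `sample_set` with standardised intensities.
#' @export
zscore_within_samples <- function(set) {
  stopifnot(inherits(set, "sample_set"), ncol(set$intensity) >= 2)
  sds <- apply(set$intensity, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant probe vector in sample(s): ",
         paste(rownames(set$intensity)[sds == 0], collapse = ", "))
  }
  set$intensity <- (set$intensity - rowMeans(set$intensity)) / sds
  set
}

#' Remove samples with exceptionally low inter-sample similarity
#'
#' Within each donor, a sample's similarity is the Pearson correlation of
#' its probe vector with the mean probe vector of the donor's other
#' samples; samples below `median - 3 * scaled MAD` of their donor's
#' similarity distribution are removed. Donors with fewer than `min_donor_n`
#' samples are skipped with a warning. Set `enabled = FALSE` for a no-op.
#'
#' @param set A `sample_set`.
#' @param n_mads Outlier cut in scaled-MAD units (default 3).
#' @param min_donor_n Minimum samples per donor (default 5).
#' @param enabled Apply the filter (default TRUE).
#' @return The filtered `sample_set`.
#' @export
filter_low_similarity_samples <- function(set, n_mads = 3, min_donor_n = 5,
                                          enabled = TRUE) {
  stopifnot(inherits(set, "sample_set"))
  if (!enabled) return(set)
  keep <- rep(TRUE, nrow(set$samples))
  for (d in unique(set$samples$donor_id)) {
    idx <- which(set$samples$donor_id == d)
    if (length(idx) < min_donor_n) {
      warning("donor ", d, " has < ", min_donor_n, " samples; skipped")
      next
    }
    M <- set$intensity[idx, , drop = FALSE]
    tot <- colSums(M)
    sim <- vapply(seq_along(idx), function(i) {
      stats::cor(M[i, ], (tot - M[i, ]) / (length(idx) - 1))
    }, numeric(1))
    cut <- stats::median(sim) - n_mads * stats::mad(sim)
    keep[idx[sim < cut]] <- FALSE
  }
  n_drop <- sum(!keep)
  if (n_drop > 0) message("filter_low_similarity_samples: removing ",
                          n_drop, " sample(s)")
  subset_samples(set, keep)
}

#' Remove probes with sparse above-threshold expression across areas
#'
#' A probe counts as expressed in an area when at least one sample assigned
#' to that area carries a present call for it. Probes expressed in fewer
#' than `fraction` of the sampled areas are removed; exactly `fraction` is
#' retained (inclusive bound). The denominator is the number of areas
#' containing at least one assigned sample.
#'
#' @param set A `sample_set`.
#' @param assignment Output of [assign_samples()].
#' @param fraction Minimum fraction of areas (default 0.40).
#' @return The filtered `sample_set`.
#' @export
filter_probes_expression <- function(set, assignment, fraction = 0.40) {
  stopifnot(inherits(set, "sample_set"))
  sidx <- match(assignment$sample_id, set$samples$sample_id)
  stopifnot(!anyNA(sidx))
  areas <- unique(assignment$area_id)
  present_in_area <- rowsum(set$calls[sidx, , drop = FALSE] + 0,
                            assignment$area_id) > 0
  n_areas_present <- colSums(present_in_area)
  keep <- n_areas_present >= fraction * length(areas)
  n_drop <- sum(!keep)
  if (n_drop > 0) message("filter_probes_expression: removing ", n_drop,
                          " probe(s) expressed in < ",
                          round(100 * fraction), "% of ", length(areas),
                          " sampled areas")
  subset_probes(set, keep)
}

#' Scaled robust sigmoid normalization
#'
#' Outlier-robust rescaling used to remove inter-donor scale differences:
#' `y = 1 / (1 + exp(-(x - median) / (IQR / 1.35)))` followed by min-max
#' rescaling of `y` to [0, 1]. The transform is invariant under positive
#' affine maps of the input and monotone throughout.
#'
#' @param x Numeric vector with at least 3 finite values and nonzero IQR.
#' @return Normalized vector in [0, 1] (NAs preserved).
#' @export
srs_normalize <- function(x) {
  ok <- is.finite(x)
  if (sum(ok) < 3) stop("need at least 3 finite values")
  iqr <- stats::IQR(x[ok])
  if (iqr == 0) stop("IQR is zero; scaled robust sigmoid undefined")
  y <- 1 / (1 + exp(-(x - stats::median(x[ok])) / (iqr / 1.35)))
  lo <- min(y[ok]); hi <- max(y[ok])
  (y - lo) / (hi - lo)
}

#' Per-area expression of one probe with nearest-sample fallback
#'
#' For each area: if at least one present-call sample is assigned within the
#' area, the area's value is the mean of those samples' intensities
#' (provenance `"direct"`). Otherwise, each vertex of the area is matched to
#' the nearest present-call sample anywhere on the mesh and the area's value
#' is the mean of those per-vertex matches, duplicates allowed (provenance
#' `"nearest-fallback"`). If no present-call sample exists at all, the cells
#' are missing.
#'
#' @param set A `sample_set`.
#' @param assignment Output of [assign_samples()] for `set`.
#' @param cortex The [generate_toy_cortex()] object used for assignment.
#' @param probe Probe id.
#' @return Tibble `area_id`, `value`, `provenance`.
#' @export
area_expression <- function(set, assignment, cortex, probe) {
  stopifnot(inherits(set, "sample_set"), probe %in% set$probes$probe_id)
  sidx <- match(assignment$sample_id, set$samples$sample_id)
  vals <- set$intensity[sidx, probe]
  pres <- set$calls[sidx, probe]
  areas <- cortex$area_ids
  out_val <- rep(NA_real_, length(areas))
  out_prov <- rep(NA_character_, length(areas))
  if (!any(pres)) {
    return(tibble::tibble(area_id = areas, value = out_val,
                          provenance = out_prov))
  }
  direct <- tapply(vals[pres], factor(assignment$area_id[pres],
                                      levels = areas), mean)
  have_direct <- !is.na(direct)
  out_val[have_direct] <- direct[have_direct]
  out_prov[have_direct] <- "direct"
  need <- which(!have_direct)
  if (length(need)) {
    pv <- assignment$vertex[pres]
    pvals <- vals[pres]
    P <- cortex$vertices[pv, , drop = FALSE]
    for (a in need) {
      vids <- which(cortex$parcel_labels == a)
      Va <- cortex$vertices[vids, , drop = FALSE]
      D2 <- outer(rowSums(Va^2), rep(1, nrow(P))) +
        outer(rep(1, nrow(Va)), rowSums(P^2)) - 2 * Va %*% t(P)
      nearest <- max.col(-D2, ties.method = "first")
      out_val[a] <- mean(pvals[nearest])
      out_prov[a] <- "nearest-fallback"
    }
  }
  tibble::tibble(area_id = areas, value = out_val, provenance = out_prov)
}

#' Choose the representative probe for a gene
#'
#' One probe: itself. Two probes: the one with maximum expression variance
#' across areas. Three or more: the one with the highest average Pearson
#' correlation (of across-area expression) with the other probes. Ties are
#' broken by probe id order; if correlations are undefined (constant
#' probes), the variance rule is used with a warning.
#'
#' @param expr Areas x probes numeric matrix for one gene's probes
#'   (colnames = probe ids).
#' @return The chosen probe id.
#' @export
representative_probe <- function(expr) {
  expr <- as.matrix(expr)
  ids <- colnames(expr)
  stopifnot(!is.null(ids), ncol(expr) >= 1, ncol(expr) <= 4)
  if (ncol(expr) == 1) return(ids[1])
  cc <- stats::complete.cases(expr)
  E <- expr[cc, , drop = FALSE]
  if (ncol(expr) == 2) {
    v <- apply(E, 2, stats::var)
    return(ids[which.max(v)])
  }
  sds <- apply(E, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant probe expression; falling back to variance rule")
    return(ids[which.max(apply(E, 2, stats::var))])
  }
  cm <- stats::cor(E)
  avg <- (rowSums(cm) - 1) / (ncol(E) - 1)
  ids[which.max(avg)]
}

#' Run the full microarray-to-parcel gene-expression pipeline
#'
#' Fixed stage order: gene-id probe filter, sample-to-vertex assignment
#' (2 mm drop rule), z-score across probes within samples, low-similarity
#' sample filter, 40%-of-areas probe expression filter, per-donor area
#' expression with nearest-sample fallback, per-donor scaled robust sigmoid
#' across areas, equal-weight donor averaging, and representative-probe
#' selection per gene.
#'
#' @param set A [generate_sample_set()] object.
#' @param cortex A [generate_toy_cortex()] object.
#' @param max_dist Sample drop threshold in mm (default 2).
#' @param expression_fraction Probe filter fraction (default 0.40).
#' @param similarity_filter Apply the low-similarity sample filter
#'   (default TRUE).
#' @return List with `expression` (tibble `area_id` x gene columns),
#'   `provenance` (same shape, `"direct"`/`"nearest-fallback"`/NA),
#'   `chosen_probes` (tibble `gene_id`, `probe_id`), `log` (named counts).
#' @export
run_gene_pipeline <- function(set, cortex, max_dist = 2,
                              expression_fraction = 0.40,
                              similarity_filter = TRUE) {
  n0_probes <- nrow(set$probes); n0_samples <- nrow(set$samples)
  set <- filter_probes_entrez(set)
  assignment <- assign_samples(set, cortex, max_dist = max_dist)
  set <- subset_samples(set, set$samples$sample_id %in% assignment$sample_id)
  assignment <- assignment[match(set$samples$sample_id,
                                 assignment$sample_id), ]
  set <- zscore_within_samples(set)
  set <- filter_low_similarity_samples(set, enabled = similarity_filter)
  assignment <- assignment[assignment$sample_id %in% set$samples$sample_id, ]
  set <- filter_probes_expression(set, assignment,
                                  fraction = expression_fraction)

  areas <- cortex$area_ids
  probes <- set$probes$probe_id
  donors <- sort(unique(set$samples$donor_id))
  # per-donor area x probe expression, SRS-normalised across areas
  donor_mats <- lapply(donors, function(d) {
    keep <- set$samples$donor_id == d
    dset <- subset_samples(set, keep)
    dassign <- assignment[assignment$donor_id == d, ]
    val <- matrix(NA_real_, length(areas), length(probes),
                  dimnames = list(areas, probes))
    prov <- matrix(NA_character_, length(areas), length(probes),
                   dimnames = list(areas, probes))
    for (p in probes) {
      ae <- area_expression(dset, dassign, cortex, p)
      v <- ae$value
      if (sum(is.finite(v)) >= 3 && stats::IQR(v[is.finite(v)]) > 0) {
        v <- srs_normalize(v)
      }
      val[, p] <- v
      prov[, p] <- ae$provenance
    }
    list(val = val, prov = prov)
  })
  val_mean <- Reduce(`+`, lapply(donor_mats, function(m) {
    v <- m$val; v[is.na(v)] <- 0; v
  })) / pmax(Reduce(`+`, lapply(donor_mats, function(m) {
    (!is.na(m$val)) + 0
  })), 1)
  n_donor <- Reduce(`+`, lapply(donor_mats, function(m) (!is.na(m$val)) + 0))
  val_mean[n_donor == 0] <- NA_real_
  prov_any <- Reduce(function(a, b) {
    ifelse(a == "direct" | b == "direct", "direct",
           ifelse(is.na(a), b, a))
  }, lapply(donor_mats, function(m) m$prov))

  genes <- unique(set$probes$gene_id)
  chosen <- purrr::map_chr(genes, function(g) {
    pids <- set$probes$probe_id[set$probes$gene_id == g]
    representative_probe(val_mean[, pids, drop = FALSE])
  })
  expr <- val_mean[, chosen, drop = FALSE]
  colnames(expr) <- genes
  prov <- prov_any[, chosen, drop = FALSE]
  colnames(prov) <- genes

  list(
    expression = tibble::as_tibble(expr, rownames = "area_id"),
    provenance = tibble::as_tibble(prov, rownames = "area_id"),
    chosen_probes = tibble::tibble(gene_id = genes, probe_id = chosen),
    log = c(probes_in = n0_probes, probes_out = length(probes),
            samples_in = n0_samples, samples_out = nrow(set$samples))
  )
}
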