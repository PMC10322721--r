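#' Planted ground truth for synthetic receptor data
#'
#' Draws the latent structure the synthetic receptor matrix is built from:
#' per-area gradient scores for `n_components` planted components, per-receptor
#' loadings, and a neuron-density map. Component 1 has strictly positive
#' loadings on every receptor (a shared density gradient, so its score tracks
#' total receptor density per neuron); component 2 is dominated by one
#' designated receptor whose |loading| is at least 3x any other (by default
#' the serotonin 5-HT1A receptor, mimicking a serotonergic secondary
#' gradient). Scores are smooth on the sphere (Gaussian random fields over
#' parcel centroids) and mutually orthogonalised. Neuron density is a smooth
#' positive map rescaled to a fixed max/min ratio (default 5, the approximate
#' range observed across primate cortex).
#'
#' @param cortex A [generate_toy_cortex()] object.
#' @param n_components Number of planted components (default 2).
#' @param noise_sd Gaussian noise SD in z-scored units added by
#'   [generate_receptor_matrix()] (stored here; default 0.2).
#' @param dominant_receptor Receptor driving component 2 (default `"5HT1A"`).
#' @param neuron_range Max/min ratio of the neuron density map (default 5).
#' @param correlation_length GRF correlation length in mm for scores
#'   (default 20).
#' @param seed Integer seed.
#' @return An object of class `planted_truth` with fields `gradient_scores`
#'   (A x K, columns orthonormalised to SD 1), `loadings` (receptors x K),
#'   `neuron_density` (per-area, neurons per gram), `noise_sd`,
#'   `dominant_receptor`, `seed`.
#' @export
planted_ground_truth <- function(cortex, n_components = 2, noise_sd = 0.2,
                                 dominant_receptor = "5HT1A",
                                 neuron_range = 5,
                                 correlation_length = 20,
                                 seed = 1) {
  stopifnot(inherits(cortex, "toy_cortex"), n_components >= 1)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  receptors <- receptor_names()
  if (!dominant_receptor %in% receptors) {
    stop("unknown receptor: ", dominant_receptor)
  }
  A <- length(cortex$area_ids)
  K <- n_components
  stopifnot(K <= min(A, length(receptors)))
  D <- distance_matrix(cortex)

  scores <- withr_seed(seed, {
    raw <- vapply(seq_len(K), function(k) {
      grf_sample(D, correlation_length)
    }, numeric(A))
    # Gram-Schmidt: orthogonal planted gradients, each centred, SD 1
    q <- qr.Q(qr(scale(raw, center = TRUE, scale = FALSE)))
    q * sqrt(A - 1)  # columns have sample SD 1
  })
  dimnames(scores) <- list(cortex$area_ids, paste0("comp", seq_len(K)))

  loadings <- withr_seed(derive_seed(seed, 2L), {
    L <- matrix(0, length(receptors), K,
                dimnames = list(receptors, paste0("comp", seq_len(K))))
    L[, 1] <- stats::runif(length(receptors), 0.6, 1.2)
    if (K >= 2) {
      L[, 2] <- stats::runif(length(receptors), -0.15, 0.15)
      L[dominant_receptor, 2] <- 0.9
    }
    if (K >= 3) {
      for (k in 3:K) L[, k] <- stats::runif(length(receptors), -0.2, 0.2)
    }
    L
  })

  # neuron density covaries with the shared gradient (as across real
  # cortex, where neuron-dense sensory areas drive common raw-density
  # patterns) plus an independent smooth component
  ndens <- withr_seed(derive_seed(seed, 3L), {
    f <- 0.7 * scores[, 1] + 0.7 * grf_sample(D, correlation_length)
    lo <- 4.0e7  # neurons per gram, low end; high end = neuron_range * lo
    lo + (f - min(f)) / (max(f) - min(f)) * lo * (neuron_range - 1)
  })
  names(ndens) <- cortex$area_ids

  structure(
    list(gradient_scores = scores, loadings = loadings,
         neuron_density = ndens, noise_sd = noise_sd,
         dominant_receptor = dominant_receptor, seed = seed),
    class = "planted_truth"
  )
}

#' Synthetic area x receptor density matrix with planted gradients
#'
#' Builds the per-neuron receptor matrix as a low-rank model plus Gaussian
#' noise in z-score space, back-transformed by per-receptor location/scale so
#' all densities are positive, and derives the raw (per mg protein) matrix by
#' the exact inverse of the per-neuron normalisation, so that
#' [per_neuron()] applied to the raw output reproduces the per-neuron output
#' to round-off.
#'
#' @param cortex A [generate_toy_cortex()] object.
#' @param truth A [planted_ground_truth()] object for the same cortex.
#' @param n_receptors Number of receptors (up to 14; default 14). The first
#'   `n_receptors` of [receptor_names()] are used.
#' @param protein_fraction Protein mass fraction used for the raw matrix
#'   (default 0.08).
#' @param seed Optional seed for the noise draw; defaults to a sub-seed of
#'   `truth$seed`.
#' @return A list with `per_neuron` and `raw` (both `receptor_matrix`
#'   tibbles, see [as_receptor_matrix()]), plus `z_truth`, the noiseless
#'   z-space matrix.
#' @export
generate_receptor_matrix <- function(cortex, truth, n_receptors = 14,
                                     protein_fraction = .protein_fraction_default,
                                     seed = NULL) {
  stopifnot(inherits(truth, "planted_truth"))
  receptors <- receptor_names()[seq_len(n_receptors)]
  K <- ncol(truth$gradient_scores)
  A <- nrow(truth$gradient_scores)
  stopifnot(K <= min(A, n_receptors))
  if (is.null(seed)) seed <- derive_seed(truth$seed, 4L)

  L <- truth$loadings[receptors, , drop = FALSE]
  Z <- truth$gradient_scores %*% t(L)  # A x R, z-ish space
  noise <- withr_seed(seed, {
    matrix(stats::rnorm(A * n_receptors, sd = truth$noise_sd), A, n_receptors)
  })
  Y <- Z + noise

  # back-transform to positive per-neuron densities (fmol per neuron):
  # per-receptor scale spans realistic magnitudes, offset keeps positivity
  scl <- 1e-4 * (1 + (seq_len(n_receptors) - 1) / 4)
  off <- vapply(seq_len(n_receptors), function(j) {
    6 * scl[j] * max(1, max(abs(Y[, j])))
  }, numeric(1))
  pn <- sweep(sweep(Y, 2, scl, `*`), 2, off, `+`)
  stopifnot(all(pn > 0))
  dimnames(pn) <- list(cortex$area_ids, receptors)

  # exact inverse of per_neuron(): raw = pn * ndens / (protein_fraction * 1000)
  raw <- pn * truth$neuron_density / (protein_fraction * .mg_per_g)

  list(
    per_neuron = as_receptor_matrix(pn, units = "fmol_per_neuron"),
    raw = as_receptor_matrix(raw, units = "fmol_per_mg_protein"),
    z_truth = Z
  )
}

#' Smooth per-parcel scalar map (Gaussian random field)
#'
#' Samples a Gaussian random field at parcel centroids with
#' squared-exponential covariance `exp(-d^2 / (2 * correlation_length^2))`.
#' As `correlation_length -> 0` the field degenerates to white noise. Used to
#' manufacture spatially autocorrelated maps for surrogate-correction tests.
#'
#' @param cortex A [generate_toy_cortex()] object.
#' @param correlation_length Correlation length in mm (> 0).
#' @param seed Integer seed.
#' @return A tibble with columns `area_id`, `value`.
#' @export
generate_smooth_map <- function(cortex, correlation_length, seed) {
  stopifnot(correlation_length > 0)
  D <- distance_matrix(cortex)
  val <- withr_seed(seed, grf_sample(D, correlation_length))
  tibble::tibble(area_id = cortex$area_ids, value = val)
}

# Draw one GRF realisation over a distance matrix (jittered Cholesky).
grf_sample <- function(D, ell) {
  K <- exp(-D^2 / (2 * ell^2))
  ch <- tryCatch(chol(K + diag(1e-8, nrow(K))),
                 error = function(e) tryCatch(
                   chol(K + diag(1e-4, nrow(K))),
                   error = function(e2) stop(
                     "covariance not positive definite after jitter")))
  as.numeric(t(ch) %*% stats::rnorm(nrow(K)))
}

#' Synthetic microarray-like sample set
#'
#' Emulates the structure of a multi-donor cortical microarray survey:
#' samples with 3D coordinates near the mesh, probe intensities built from
#' planted per-area gene maps plus donor, probe and residual Gaussian
#' offsets, per-sample/probe present-absent calls, and a valid-gene-id flag
#' per probe. Coordinates are jittered off the surface so a known fraction of
#' samples fall beyond the 2 mm assignment threshold downstream.
#'
#' @param cortex A [generate_toy_cortex()] object.
#' @param n_donors,n_samples_per_donor,n_probes,n_genes Survey dimensions.
#'   Every gene owns 1-4 probes; `n_genes` must not exceed `n_probes`.
#' @param planted_gene_maps Numeric A x `n_genes` matrix of per-area
#'   expression (rownames = area ids); if `NULL`, smooth maps are drawn.
#' @param call_rate Probability that an expressing sample-probe pair gets a
#'   "present" call (default 0.8).
#' @param coord_noise_sd Gaussian SD (mm) of the off-surface coordinate
#'   jitter (default 1).
#' @param donor_sd,probe_sd,noise_sd SDs of donor offsets, probe offsets and
#'   residual noise, in planted-map units.
#' @param valid_id_rate Fraction of probes carrying a valid gene-identifier
#'   flag (default 0.9).
#' @param seed Integer seed.
#' @return An object of class `sample_set`: list with `samples` (tibble:
#'   `sample_id`, `donor_id`, `x`, `y`, `z`, `true_vertex`, `true_area`),
#'   `probes` (tibble: `probe_id`, `gene_id`, `entrez_valid`), `intensity`
#'   (samples x probes matrix), `calls` (logical matrix, same shape), and
#'   `planted_gene_maps`.
#' @export
generate_sample_set <- function(cortex, n_donors, n_samples_per_donor,
                                n_probes, n_genes,
                                planted_gene_maps = NULL,
                                call_rate = 0.8, coord_noise_sd = 1,
                                donor_sd = 0.5, probe_sd = 0.3,
                                noise_sd = 0.2, valid_id_rate = 0.9,
                                seed = 1) {
  if (n_genes > n_probes) stop("n_genes must be <= n_probes")
  stopifnot(call_rate >= 0, call_rate <= 1, coord_noise_sd >= 0)
  A <- length(cortex$area_ids)
  if (is.null(planted_gene_maps)) {
    planted_gene_maps <- withr_seed(derive_seed(seed, 10L), {
      vapply(seq_len(n_genes), function(g) grf_sample(
        distance_matrix(cortex), 20), numeric(A))
    })
    dimnames(planted_gene_maps) <- list(cortex$area_ids,
                                        paste0("G", seq_len(n_genes)))
  }
  stopifnot(nrow(planted_gene_maps) == A, ncol(planted_gene_maps) == n_genes)

  # probes per gene: every gene gets one, leftovers spread with cap 4
  gene_of_probe <- withr_seed(derive_seed(seed, 11L), {
    counts <- rep(1L, n_genes)
    extra <- n_probes - n_genes
    while (extra > 0) {
      cand <- which(counts < 4L)
      if (!length(cand)) stop("cannot place ", n_probes,
                              " probes on ", n_genes, " genes (max 4 each)")
      pick <- cand[sample.int(length(cand), 1)]
      counts[pick] <- counts[pick] + 1L
      extra <- extra - 1L
    }
    rep(seq_len(n_genes), counts)
  })

  ns <- n_donors * n_samples_per_donor
  withr_seed(derive_seed(seed, 12L), {
    vtx <- sample.int(nrow(cortex$vertices), ns, replace = TRUE)
    coords <- cortex$vertices[vtx, , drop = FALSE] +
      matrix(stats::rnorm(ns * 3, sd = coord_noise_sd), ns, 3)
    donor <- rep(seq_len(n_donors), each = n_samples_per_donor)
    donor_off <- stats::rnorm(n_donors, sd = donor_sd)
    probe_off <- stats::rnorm(n_probes, sd = probe_sd)
    area <- cortex$parcel_labels[vtx]
    base <- planted_gene_maps[area, gene_of_probe, drop = FALSE]
    intensity <- base +
      matrix(donor_off[donor], ns, n_probes) +
      matrix(probe_off, ns, n_probes, byrow = TRUE) +
      matrix(stats::rnorm(ns * n_probes, sd = noise_sd), ns, n_probes)
    calls <- matrix(stats::runif(ns * n_probes) < call_rate, ns, n_probes)
    entrez <- stats::runif(n_probes) < valid_id_rate
    sample_ids <- sprintf("S%04d", seq_len(ns))
    probe_ids <- sprintf("P%04d", seq_len(n_probes))
    dimnames(intensity) <- list(sample_ids, probe_ids)
    dimnames(calls) <- list(sample_ids, probe_ids)
    structure(
      list(
        samples = tibble::tibble(
          sample_id = sample_ids,
          donor_id = sprintf("D%02d", donor),
          x = coords[, 1], y = coords[, 2], z = coords[, 3],
          true_vertex = vtx,
          true_area = cortex$area_ids[area]
        ),
        probes = tibble::tibble(
          probe_id = probe_ids,
          gene_id = paste0("G", gene_of_probe),
          entrez_valid = entrez
        ),
        intensity = intensity,
        calls = calls,
        planted_gene_maps = planted_gene_maps,
        seed = seed
      ),
      class = "sample_set"
    )
  })
}

#' @export
print.sample_set <- function(x, ...) {
  cat("<sample_set> ", nrow(x$samples), " samples / ",
      length(unique(x$samples$donor_id)), " donors, ",
      nrow(x$probes), " probes / ",
      length(unique(x$probes$gene_id)), " genes\n", sep = "")
  invisible(x)
}

#' Synthetic functional activation z-map planted in a gradient band
#'
#' Produces a vertex-level z-map whose supra-threshold (z > 3.1) vertices lie
#' predominantly where the supplied gradient map's vertex percentile falls in
#' `band`; the known ground-truth embedding position is the band midpoint.
#'
#' @param cortex A [generate_toy_cortex()] object.
#' @param gradient_map Tibble (`area_id`, `value`) or named per-area vector;
#'   painted piecewise-constant onto vertices.
#' @param band Numeric `c(lo, hi)` percentile band, `0 <= lo < hi <= 100`.
#' @param z_peak Peak z-value inside the band (default 6).
#' @param noise_sd SD of additive vertex noise (default 0.5; use 0 for a
#'   noiseless map).
#' @param seed Integer seed.
#' @return A tibble with columns `vertex`, `z`.
#' @export
generate_functional_map <- function(cortex, gradient_map, band,
                                    z_peak = 6, noise_sd = 0.5, seed = 1) {
  stopifnot(length(band) == 2)
  if (!(band[1] >= 0 && band[2] <= 100 && band[1] < band[2])) {
    stop("band must satisfy 0 <= lo < hi <= 100")
  }
  g <- paint_vertices(cortex, gradient_map)
  pct <- (rank(g, ties.method = "first") - 0.5) / length(g) * 100
  inside <- pct > band[1] & pct <= band[2]
  if (!any(inside)) stop("band contains no vertices")
  z <- withr_seed(seed, {
    base <- stats::rnorm(length(g), mean = 0, sd = max(noise_sd, 1e-12))
    base[inside] <- base[inside] + z_peak
    if (noise_sd == 0) {
      base <- ifelse(inside, z_peak, 0)
    }
    base
  })
  tibble::tibble(vertex = seq_along(z), z = z)
}

# Paint a per-area map onto vertices (piecewise constant over parcels).
paint_vertices <- function(cortex, area_map) {
  v <- as_area_vector(area_map, cortex$area_ids)
  v[cortex$parcel_labels]
}

# Accept tibble(area_id, value) or a named/plain numeric vector.
as_area_vector <- function(map, area_ids) {
  if (is.data.frame(map)) {
    stopifnot(all(c("area_id", "value") %in% names(map)))
    v <- map$value[match(area_ids, map$area_id)]
  } else if (!is.null(names(map))) {
    v <- unname(map[area_ids])
  } else {
    stopifnot(length(map) == length(area_ids))
    v <- as.numeric(map)
  }
  names(v) <- area_ids
  v
}
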