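#' Default pipeline configuration
#'
#' Assembles the run configuration: synthetic-data sizes, stage thresholds
#' (functional z cutoff 3.1, limbic-exclusion overlap 0.5, 2 mm sample
#' drop distance, 0.40 probe expression fraction, 0.08 protein fraction),
#' surrogate count, Dice bin count, seeds and output directory. Every
#' stochastic stage derives its seed deterministically from the one global
#' `seed`. The list round-trips losslessly through [yaml::as.yaml()]-style
#' serialisation (plain atomic fields only).
#'
#' @param seed Global integer seed.
#' @param out_dir Output directory.
#' @param ... Overrides for any default field.
#' @return A named list of class `run_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("receptor_run"),
                            ...) {
  cfg <- list(
    seed = seed,
    out_dir = out_dir,
    n_areas = 60,
    mesh_resolution = 4,
    n_receptors = 14,
    noise_sd = 0.2,
    n_surrogates = 200,
    n_bins = 20,
    z_threshold = 3.1,
    limbic_threshold = 0.5,
    max_dist = 2,
    expression_fraction = 0.40,
    protein_fraction = 0.08,
    n_donors = 6,
    n_samples_per_donor = 100,
    n_probes = 40,
    n_genes = 20,
    surrogate_seed = NA
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = c("run_config", "list"))
}

#' Run the synthetic end-to-end receptor-gradient pipeline
#'
#' Generates a toy cortex and every synthetic input, then executes the
#' stages in dependency order: per-neuron normalisation, z-scoring and PCA
#' gradients, gradient-dependence table, network summaries, surrogate-based
#' correlation of PC1 with a smooth comparison map, Dice embedding of a
#' planted functional map, and the gene-expression pipeline. Each stage's
#' table is written as a tab-separated UTF-8 file under `config$out_dir`,
#' and a manifest records file MD5 hashes, seeds and row counts. Reruns
#' with an identical config reproduce identical hashes.
#'
#' @param config A [pipeline_config()] list.
#' @return Invisibly, a list with `manifest` (tibble `file`, `md5`,
#'   `n_rows`), `results` (in-memory stage outputs), `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  cortex <- generate_toy_cortex(config$n_areas, config$mesh_resolution,
                                seed = config$seed)
  truth <- planted_ground_truth(cortex, noise_sd = config$noise_sd,
                                seed = derive_seed(config$seed, 21L))
  mats <- generate_receptor_matrix(cortex, truth,
                                   n_receptors = config$n_receptors,
                                   protein_fraction = config$protein_fraction)
  pn <- per_neuron(mats$raw, truth$neuron_density,
                   protein_fraction = config$protein_fraction)
  fit <- receptor_pca(zscore_columns(pn))
  dep <- dependence_table(fit, max_pc = min(5, config$n_receptors))
  nets <- network_table(cortex,
                        exclusion_threshold = config$limbic_threshold)
  pc1_vertex <- paint_vertices(cortex, stats::setNames(
    fit$scores[, 1], rownames(fit$scores)))
  netsum <- network_summary(pc1_vertex, cortex)

  cmp_map <- generate_smooth_map(cortex, correlation_length = 20,
                                 seed = derive_seed(config$seed, 22L))
  D <- distance_matrix(cortex)
  pc1_map <- tibble::tibble(area_id = rownames(fit$scores),
                            value = fit$scores[, 1])
  surr_seed <- if (is.na(config$surrogate_seed)) {
    derive_seed(config$seed, 23L)
  } else {
    config$surrogate_seed
  }
  ens <- make_surrogates(pc1_map, D, n_surr = config$n_surrogates,
                         seed = surr_seed)
  corr <- corrected_correlation(pc1_map, cmp_map, ens)
  corr$p_bonferroni <- bonferroni(corr$p_spatial, m = 1)

  fmap <- generate_functional_map(cortex, pc1_map, band = c(40, 60),
                                  z_peak = 6,
                                  seed = derive_seed(config$seed, 24L))
  emb <- dice_embedding(binarize(fmap, config$z_threshold), pc1_vertex,
                        n_bins = config$n_bins)

  sset <- generate_sample_set(cortex, config$n_donors,
                              config$n_samples_per_donor,
                              config$n_probes, config$n_genes,
                              seed = derive_seed(config$seed, 25L))
  genes <- run_gene_pipeline(sset, cortex, max_dist = config$max_dist,
                             expression_fraction = config$expression_fraction)

  results <- list(
    cortex = cortex, truth = truth, receptor_per_neuron = pn,
    receptor_raw = mats$raw, pca = fit, dependence = dep,
    networks = nets, network_summary = netsum$summary,
    correlation = corr, embedding = emb, genes = genes
  )

  files <- list(
    receptor_per_neuron = tibble::as_tibble(pn),
    receptor_raw = tibble::as_tibble(mats$raw),
    pc_scores = tibble::as_tibble(fit$scores,
                                  rownames = "area_id"),
    pc_loadings = tibble::as_tibble(fit$loadings,
                                    rownames = "receptor"),
    variance_fractions = tibble::tibble(
      pc = seq_along(fit$variance_fraction),
      variance_fraction = fit$variance_fraction),
    dependence = dep,
    network_table = nets,
    network_summary = netsum$summary,
    correlation_report = corr,
    dice_embedding = tibble::as_tibble(emb),
    gene_expression = genes$expression
  )
  paths <- character(0)
  for (nm in names(files)) {
    p <- file.path(config$out_dir, paste0(nm, ".tsv"))
    utils::write.table(files[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    paths[nm] <- p
  }
  manifest <- tibble::tibble(
    file = basename(paths),
    md5 = unname(tools::md5sum(paths)),
    n_rows = vapply(files, nrow, integer(1))
  )
  utils::write.table(manifest, file.path(config$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(manifest = manifest, results = results, config = config))
}

#' Correlation report for a declared family of map pairs
#'
#' Correlates each gradient map against each declared comparison map with
#' the surrogate-corrected p-value, then Bonferroni-adjusts with `m` equal
#' to the number of declared pairs. One surrogate ensemble is built per
#' gradient map and reused across its comparisons.
#'
#' @param gradients Named list of per-area maps (tibble or named vector).
#' @param comparisons Named list of per-area maps.
#' @param D Distance matrix from [distance_matrix()].
#' @param n_surr Surrogates per ensemble (default 1000).
#' @param seed Integer seed.
#' @return Tibble `gradient`, `comparison`, `r`, `ci_lo`, `ci_hi`,
#'   `p_spatial`, `p_bonferroni`, `n`; attribute `m` records the family
#'   size.
#' @export
report_correlations <- function(gradients, comparisons, D,
                                n_surr = 1000, seed = 1) {
  stopifnot(length(gradients) >= 1, length(comparisons) >= 1,
            !is.null(names(gradients)), !is.null(names(comparisons)))
  m <- length(gradients) * length(comparisons)
  rows <- purrr::imap_dfr(gradients, function(g, gname) {
    ens <- make_surrogates(g, D, n_surr = n_surr,
                           seed = derive_seed(seed, match(gname,
                                                          names(gradients))))
    purrr::imap_dfr(comparisons, function(cmp, cname) {
      cc <- corrected_correlation(g, cmp, ens)
      tibble::tibble(gradient = gname, comparison = cname,
                     r = cc$r, ci_lo = cc$ci_lo, ci_hi = cc$ci_hi,
                     p_spatial = cc$p_spatial, n = cc$n)
    })
  })
  rows$p_bonferroni <- bonferroni(rows$p_spatial, m = m)
  attr(rows, "m") <- m
  rows
}
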