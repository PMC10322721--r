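make_small_set <- function(cx, ...) {
  generate_sample_set(cx, n_donors = 2, n_samples_per_donor = 25,
                      n_probes = 12, n_genes = 6, seed = 17, ...)
}

test_that("gene-id probe filtering drops exactly the unflagged probes", {
  cx <- tc8()
  ss <- make_small_set(cx, valid_id_rate = 1)
  expect_identical(suppressMessages(filter_probes_entrez(ss))$probes,
                   ss$probes)
  ss2 <- ss
  ss2$probes$entrez_valid[c(2, 5, 9)] <- FALSE
  out <- suppressMessages(filter_probes_entrez(ss2))
  expect_equal(nrow(out$probes), 9)
  expect_equal(ncol(out$intensity), 9)
  expect_false(any(c("P0002", "P0005", "P0009") %in% out$probes$probe_id))
  ss3 <- ss
  ss3$probes$entrez_valid[] <- FALSE
  expect_error(filter_probes_entrez(ss3), "all probes")
})

test_that("sample assignment enforces the distance and collision rules", {
  cx <- tc8()
  ss <- make_small_set(cx, coord_noise_sd = 0)
  asn <- assign_samples(ss, cx)
  expect_identical(attr(asn, "n_dropped"), 0L)
  # zero jitter: assignments match the brute-force nearest vertex wherever
  # no collision forced a move
  S <- as.matrix(ss$samples[, c("x", "y", "z")])
  nearest <- apply(S, 1, function(p) {
    which.min(colSums((t(cx$vertices) - p)^2))
  })
  moved <- asn$vertex != nearest[match(asn$sample_id, ss$samples$sample_id)]
  expect_lt(mean(moved), 0.5)
  expect_true(all(asn$dist[!moved] < 1e-4))
  # one sample per vertex
  expect_false(anyDuplicated(asn$vertex) > 0)

  # an off-surface sample beyond 2 mm is dropped
  ss2 <- ss
  ss2$samples$x[1] <- ss2$samples$x[1] + 50
  expect_message(asn2 <- assign_samples(ss2, cx), "dropping 1")
  expect_false(ss$samples$sample_id[1] %in% asn2$sample_id)

  # collision: the later sample (by donor, sample id) takes the next vertex
  ss3 <- ss
  ss3$samples$x[2] <- ss3$samples$x[1]
  ss3$samples$y[2] <- ss3$samples$y[1]
  ss3$samples$z[2] <- ss3$samples$z[1]
  asn3 <- assign_samples(ss3, cx)
  v1 <- asn3$vertex[asn3$sample_id == ss3$samples$sample_id[1]]
  v2 <- asn3$vertex[asn3$sample_id == ss3$samples$sample_id[2]]
  expect_equal(v1, nearest[1])
  expect_true(v2 != v1)
})

test_that("within-sample z-scoring standardises each probe vector", {
  cx <- tc8()
  ss <- make_small_set(cx)
  ss$intensity[1, ] <- rep(c(1, 2, 3), 4)
  out <- zscore_within_samples(ss)
  expect_equal(unname(rowMeans(out$intensity)),
               rep(0, nrow(out$intensity)), tolerance = 1e-12)
  expect_equal(unname(apply(out$intensity, 1, sd)),
               rep(1, nrow(out$intensity)), tolerance = 1e-12)
  ssc <- ss
  ssc$intensity[3, ] <- 5
  expect_error(zscore_within_samples(ssc), "S0003")
})

test_that("the low-similarity filter removes a planted outlier only", {
  cx <- tc8()
  ss <- make_small_set(cx)
  set.seed(18)
  base <- rnorm(ncol(ss$intensity))
  # identical samples: every similarity is 1, nothing removed
  ss$intensity[] <- rep(base, each = nrow(ss$intensity))
  expect_equal(nrow(filter_low_similarity_samples(ss)$samples),
               nrow(ss$samples))
  # coherent samples plus one independent-noise outlier
  ss2 <- ss
  ss2$intensity <- ss2$intensity +
    matrix(rnorm(length(ss2$intensity), sd = 0.1), nrow(ss2$intensity))
  ss2$intensity[7, ] <- rnorm(ncol(ss2$intensity))
  out <- suppressMessages(filter_low_similarity_samples(ss2))
  expect_false("S0007" %in% out$samples$sample_id)
  expect_equal(nrow(out$samples), nrow(ss$samples) - 1)
  # disabled: identity
  expect_identical(filter_low_similarity_samples(ss2, enabled = FALSE), ss2)
  # small donors are skipped with a warning
  ss3 <- generate_sample_set(cx, 1, 3, 6, 3, seed = 4)
  expect_warning(filter_low_similarity_samples(ss3), "skipped")
})

test_that("the expression filter applies an inclusive 40% area rule", {
  cx <- tc8()
  ss <- make_small_set(cx, coord_noise_sd = 0)
  asn <- assign_samples(ss, cx)
  sampled_areas <- unique(asn$area_id)
  n_areas <- length(sampled_areas)
  # craft calls: probe 1 present in exactly 40% of areas, probe 2 below
  k_keep <- ceiling(0.4 * n_areas)
  ss$calls[] <- TRUE
  sidx <- match(asn$sample_id, ss$samples$sample_id)
  areas_of_samples <- asn$area_id
  in_first_k <- areas_of_samples %in% sampled_areas[seq_len(k_keep)]
  ss$calls[sidx, 1] <- in_first_k
  ss$calls[sidx, 2] <- areas_of_samples %in%
    sampled_areas[seq_len(max(k_keep - 1, 1))]
  out <- suppressMessages(
    filter_probes_expression(ss, asn, fraction = k_keep / n_areas))
  expect_true("P0001" %in% out$probes$probe_id)
  expect_false("P0002" %in% out$probes$probe_id)
})

test_that("scaled robust sigmoid matches its formula and invariances", {
  x <- c(0, 1, 2, 3, 10)
  y <- srs_normalize(x)
  # direct evaluation of the formula
  med <- median(x); iqr <- IQR(x)
  raw <- 1 / (1 + exp(-(x - med) / (iqr / 1.35)))
  expect_equal(y, (raw - min(raw)) / (max(raw) - min(raw)), tolerance = 1e-12)
  expect_true(all(y >= 0 & y <= 1))
  # the sigmoid is centred at the median before min-max rescaling
  expect_equal(raw[x == med], 0.5)
  # positive affine invariance
  expect_equal(srs_normalize(3 * x + 7), y, tolerance = 1e-12)
  # monotone
  expect_true(all(diff(y[order(x)]) >= 0))
  expect_error(srs_normalize(c(1, 1, 1, 1)), "IQR")
  expect_error(srs_normalize(c(1, 2)), "3 finite")
})

test_that("area expression uses direct means with nearest-sample fallback", {
  cx <- tc8()
  ss <- make_small_set(cx, coord_noise_sd = 0, call_rate = 1)
  asn <- assign_samples(ss, cx)
  p <- ss$probes$probe_id[1]
  # direct: area containing two present samples valued 1 and 3
  a_direct <- asn$area_id[1]
  in_area <- asn$area_id == a_direct
  sidx <- match(asn$sample_id, ss$samples$sample_id)
  ss$calls[, p] <- FALSE
  two <- which(in_area)[1:2]
  ss$calls[sidx[two], p] <- TRUE
  ss$intensity[sidx[two], p] <- c(1, 3)
  ae <- area_expression(ss, asn, cx, p)
  expect_equal(ae$value[ae$area_id == a_direct], 2)
  expect_equal(ae$provenance[ae$area_id == a_direct], "direct")
  # all other areas: fallback to nearest present-call samples
  others <- setdiff(cx$area_ids, a_direct)
  expect_true(all(ae$provenance[ae$area_id %in% others] ==
                    "nearest-fallback"))
  # single present sample: every fallback area inherits it exactly
  ss2 <- ss
  ss2$calls[, p] <- FALSE
  ss2$calls[sidx[two][1], p] <- TRUE
  ss2$intensity[sidx[two][1], p] <- 5
  ae2 <- area_expression(ss2, asn, cx, p)
  fb <- ae2$area_id != a_direct
  expect_true(all(ae2$value[fb] == 5))
  # exhaustive per-vertex nearest-sample oracle on a random call pattern
  ss3 <- make_small_set(cx, coord_noise_sd = 0)
  asn3 <- assign_samples(ss3, cx)
  p3 <- ss3$probes$probe_id[2]
  ae3 <- area_expression(ss3, asn3, cx, p3)
  sidx3 <- match(asn3$sample_id, ss3$samples$sample_id)
  pres <- which(ss3$calls[sidx3, p3])
  for (a in which(is.na(match(cx$area_ids, asn3$area_id[pres])))) {
    vids <- which(cx$parcel_labels == a)
    vals <- vapply(vids, function(vv) {
      dd <- colSums((t(cx$vertices[asn3$vertex[pres], , drop = FALSE]) -
                       cx$vertices[vv, ])^2)
      ss3$intensity[sidx3[pres[which.min(dd)]], p3]
    }, numeric(1))
    expect_equal(ae3$value[a], mean(vals), tolerance = 1e-12)
  }
})

test_that("representative probes follow the variance and correlation rules", {
  expect_equal(representative_probe(matrix(1:5, 5, 1,
    dimnames = list(NULL, "P1"))), "P1")
  set.seed(19)
  two <- cbind(P1 = rnorm(20, sd = sqrt(1.2)), P2 = rnorm(20, sd = sqrt(0.4)))
  expect_equal(representative_probe(two),
               c("P1", "P2")[which.max(apply(two, 2, var))])
  # three probes: two near-duplicates beat an independent noise probe
  base <- rnorm(30)
  three <- cbind(P1 = base + rnorm(30, sd = 0.05),
                 P2 = base + rnorm(30, sd = 0.05),
                 P3 = rnorm(30))
  expect_true(representative_probe(three) %in% c("P1", "P2"))
  # degenerate: constant probes fall back to the variance rule
  cst <- cbind(P1 = rep(1, 10), P2 = rep(2, 10), P3 = rnorm(10))
  expect_warning(chosen <- representative_probe(cst), "variance rule")
  expect_equal(chosen, "P3")
})

test_that("the full gene pipeline recovers planted maps", {
  cx <- tc60()
  ss <- generate_sample_set(cx, 6, 100, 40, 20, seed = 11)
  res <- suppressMessages(run_gene_pipeline(ss, cx))
  E <- as.matrix(res$expression[-1])
  rownames(E) <- res$expression$area_id
  pl <- ss$planted_gene_maps
  rs <- vapply(intersect(colnames(E), colnames(pl)), function(g) {
    cor(E[, g], pl[rownames(E), g], use = "complete.obs")
  }, numeric(1))
  expect_gte(mean(rs), 0.8)
  # provenance set for every non-missing cell
  P <- as.matrix(res$provenance[-1])[, res$chosen_probes$gene_id[1]]
  expect_true(all(!is.na(P[!is.na(E[, res$chosen_probes$gene_id[1]])])))
  # SRS output range respected
  expect_true(all(E >= -1e-9 & E <= 1 + 1e-9, na.rm = TRUE))
})
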