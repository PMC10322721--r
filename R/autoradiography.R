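#' Ligand incubation and counting parameters
#'
#' Bundles the constants of the densitometry calibration equation:
#' `E` scintillation-counter efficiency (fraction, <= 1), `B` decays per
#' unit time and radioactivity (Ci min^-1 convention), `S_a` specific
#' activity of the ligand (Ci mmol^-1), `K_D` dissociation constant (nM) and
#' `L` incubation ligand concentration (nM). All must be strictly positive.
#'
#' @param E,B,S_a,K_D,L See description.
#' @return A `ligand_params` list.
#' @export
ligand_params <- function(E, B, S_a, K_D, L) {
  vals <- c(E = E, B = B, S_a = S_a, K_D = K_D, L = L)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all ligand parameters must be finite and strictly positive")
  }
  if (E > 1) stop("counter efficiency E must be <= 1")
  structure(list(E = E, B = B, S_a = S_a, K_D = K_D, L = L),
            class = "ligand_params")
}

#' Binding-site concentration of a radioactive standard
#'
#' Converts a standard's measured radioactivity into a binding-site
#' concentration (fmol per mg of protein):
#' `C_b = R / (E * B * W_b * S_a) * (K_D + L) / L`.
#' The first factor converts counts to mol of ligand per mg protein; the
#' saturation correction `(K_D + L) / L` extrapolates the occupied fraction
#' of sites at ligand concentration `L` to the full site population. The
#' result is linear (homogeneous of degree 1) in `R` and of degree -1 in
#' each of `E`, `B`, `W_b`, `S_a`.
#'
#' @param R Radioactivity, counts per minute (>= 0); vectorised.
#' @param W_b Protein weight of the standard (mg, > 0).
#' @param params A [ligand_params()] object.
#' @return Concentration(s) `C_b`, fmol per mg protein.
#' @examples
#' p <- ligand_params(E = 0.5, B = 10, S_a = 5, K_D = 1, L = 1)
#' standard_concentration(100, W_b = 2, params = p)  # 4
#' @export
standard_concentration <- function(R, W_b, params) {
  stopifnot(inherits(params, "ligand_params"))
  if (any(R < 0)) stop("radioactivity R must be >= 0")
  if (any(W_b <= 0)) stop("protein weight W_b must be > 0")
  R / (params$E * params$B * W_b * params$S_a) *
    (params$K_D + params$L) / params$L
}

#' Fit a gray-value to concentration calibration curve
#'
#' Autoradiographs are digitised as 8-bit images; co-exposed standards of
#' known radioactivity relate film gray values to binding-site
#' concentrations. Standard radioactivities are converted via
#' [standard_concentration()] and a monotone piecewise-cubic
#' (Fritsch-Carlson) interpolant is fit through the (gray, C_b) knots: exact
#' at every standard, monotone in between, and free of the oscillation a
#' plain cubic spline would introduce into a saturating film response.
#' Evaluation outside the standards' gray range clamps to the nearest knot
#' value with a warning — film saturates, so extrapolation is unphysical.
#'
#' @param standards Data frame with columns `gray` (0-255, distinct), `R`
#'   (counts per minute) and `W_b` (mg); at least 4 rows.
#' @param params A [ligand_params()] object.
#' @return A `calibration_curve` object; evaluate with
#'   [linearize_image()] or `predict()`.
#' @export
fit_calibration_curve <- function(standards, params) {
  stopifnot(is.data.frame(standards),
            all(c("gray", "R", "W_b") %in% names(standards)))
  if (nrow(standards) < 4) stop("need at least 4 standards")
  if (any(standards$gray < 0 | standards$gray > 255)) {
    stop("gray values must lie in 0-255")
  }
  if (anyDuplicated(standards$gray)) {
    stop("duplicate gray values among standards")
  }
  cb <- standard_concentration(standards$R, standards$W_b, params)
  ord <- order(standards$gray)
  g <- standards$gray[ord]
  cb <- cb[ord]
  d <- diff(cb)
  if (!(all(d > 0) || all(d < 0))) {
    i <- which(diff(sign(d)) != 0)[1] + 1L
    stop("standards are not jointly monotone in gray and concentration ",
         "(offending pair: gray ", g[i], " -> ", g[i + 1L], ")")
  }
  f <- stats::splinefun(g, cb, method = "monoH.FC")
  structure(list(knots = tibble::tibble(gray = g, C_b = cb),
                 fun = f, gray_range = range(g)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration_curve> ", nrow(x$knots), " standards, gray ",
      x$gray_range[1], "-", x$gray_range[2], ", C_b ",
      signif(min(x$knots$C_b), 4), "-", signif(max(x$knots$C_b), 4),
      " fmol/mg protein\n", sep = "")
  invisible(x)
}

#' @param object A `calibration_curve`.
#' @param gray Gray values to evaluate.
#' @param ... Unused.
#' @rdname fit_calibration_curve
#' @export
predict.calibration_curve <- function(object, gray, ...) {
  lo <- object$gray_range[1]; hi <- object$gray_range[2]
  n_out <- sum(gray < lo | gray > hi, na.rm = TRUE)
  if (n_out > 0) {
    warning(n_out, " gray value(s) outside the calibrated range [",
            lo, ", ", hi, "]; clamped to nearest knot")
  }
  object$fun(pmin(pmax(gray, lo), hi))
}

#' Linearize an autoradiograph
#'
#' Applies the calibration curve element-wise, converting each pixel's gray
#' value into a binding-site concentration. Shape and dimnames are
#' preserved; monotone curves preserve the ordering of pixel values.
#'
#' @param gray_image Numeric matrix (or array) of 8-bit gray values.
#' @param curve A [fit_calibration_curve()] result.
#' @return Concentration image, fmol per mg protein, same shape.
#' @export
linearize_image <- function(gray_image, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  out <- predict(curve, as.numeric(gray_image))
  dim(out) <- dim(gray_image)
  dimnames(out) <- dimnames(gray_image)
  out
}

#' Laminar density profile from a linearized section
#'
#' Averages a rectified 2D concentration patch (rows = cortical depth,
#' columns = tangential position) into `n_bins` depth bins between the pial
#' surface row and the white-matter row. Depth is expressed as percent of
#' the pial-to-white distance (0 = pial). Each bin's density is the mean
#' concentration over its row band and the stated columns. Curvilinear
#' traversal of folded cortex is out of scope: patches are assumed
#' rectified.
#'
#' @param conc_image Numeric matrix of concentrations.
#' @param pial_row,wm_row Row indices bounding the cortical ribbon
#'   (`pial_row < wm_row`).
#' @param columns Column index range to average over (default all).
#' @param n_bins Number of depth bins (>= 5, default 10).
#' @return A `laminar_profile` tibble: `bin`, `depth_lo`, `depth_hi`
#'   (percent), `density`; attribute `n_columns`.
#' @export
laminar_profile <- function(conc_image, pial_row, wm_row,
                            columns = seq_len(ncol(conc_image)),
                            n_bins = 10) {
  stopifnot(pial_row < wm_row, n_bins >= 5)
  if (length(columns) == 0) stop("empty column range")
  rows <- pial_row:wm_row
  frac <- (seq_along(rows) - 0.5) / length(rows)
  bin <- pmin(ceiling(frac * n_bins), n_bins)
  patch <- conc_image[rows, columns, drop = FALSE]
  dens <- as.numeric(rowsum(rowMeans(patch), bin) / tabulate(bin, n_bins))
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    depth_lo = (seq_len(n_bins) - 1) / n_bins * 100,
    depth_hi = seq_len(n_bins) / n_bins * 100,
    density = dens
  )
  attr(out, "n_columns") <- length(columns)
  class(out) <- c("laminar_profile", class(out))
  out
}

#' Mean area density and replicate coefficient of variation
#'
#' Collapses 3-5 laminar profiles (sections) of one area/receptor/brain to a
#' single mean density — the mean over sections of each profile's
#' depth-averaged density — plus the between-section coefficient of
#' variation (sample SD over mean). Counts outside 3-5 raise a warning but
#' proceed; a single section yields `cov = NA`.
#'
#' @param profiles List of [laminar_profile()] tibbles, or a numeric vector
#'   of per-section depth-averaged densities.
#' @return Tibble with `mean_density`, `cov`, `n_sections`.
#' @export
area_mean_density <- function(profiles) {
  if (is.numeric(profiles)) {
    sect <- profiles
  } else {
    sect <- vapply(profiles, function(p) mean(p$density), numeric(1))
  }
  n <- length(sect)
  if (n < 3 || n > 5) {
    warning("expected 3-5 sections per area/receptor/brain, got ", n)
  }
  m <- mean(sect)
  if (n >= 2 && m == 0) stop("mean density is zero; CoV undefined")
  cv <- if (n >= 2) stats::sd(sect) / m else NA_real_
  tibble::tibble(mean_density = m, cov = cv, n_sections = n)
}

#' Median coefficient of variation across a replicate cohort
#'
#' Quality-control summary of densitometry reproducibility: per
#' (area, receptor) cell the CoV (sample SD / mean) across replicates —
#' sections within a brain, or subjects — then the median over all cells.
#' Cells with fewer than 2 finite replicates are skipped and counted.
#'
#' @param densities Long tibble with columns `area_id`, `receptor`,
#'   `replicate`, `density`, or a 3-d array `[area, receptor, replicate]`.
#' @return Tibble with `median_cov`, `n_cells`, `n_skipped`.
#' @export
cohort_cov_summary <- function(densities) {
  if (is.array(densities) && length(dim(densities)) == 3) {
    densities <- array_to_long(densities)
  }
  stopifnot(all(c("area_id", "receptor", "density") %in% names(densities)))
  cell <- densities |>
    dplyr::group_by(.data$area_id, .data$receptor) |>
    dplyr::summarise(
      n = sum(is.finite(.data$density)),
      cov = if (sum(is.finite(.data$density)) >= 2) {
        x <- .data$density[is.finite(.data$density)]
        stats::sd(x) / mean(x)
      } else NA_real_,
      .groups = "drop"
    )
  usable <- cell$n >= 2
  if (!any(usable)) stop("no (area, receptor) cell has >= 2 replicates")
  n_skipped <- sum(!usable)
  if (n_skipped > 0) message("cohort_cov_summary: skipping ", n_skipped,
                             " cell(s) with < 2 replicates")
  tibble::tibble(median_cov = stats::median(cell$cov[usable]),
                 n_cells = sum(usable), n_skipped = n_skipped)
}

array_to_long <- function(a) {
  dn <- dimnames(a) %||% list(NULL, NULL, NULL)
  area <- dn[[1]] %||% sprintf("A%03d", seq_len(dim(a)[1]))
  rec <- dn[[2]] %||% sprintf("R%02d", seq_len(dim(a)[2]))
  rep_ <- dn[[3]] %||% seq_len(dim(a)[3])
  # expand_grid varies the last column fastest, matching column-major layout
  tidyr::expand_grid(replicate = rep_, receptor = rec, area_id = area) |>
    dplyr::mutate(density = as.numeric(a))
}
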