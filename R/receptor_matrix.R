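#' Area x receptor density table
#'
#' The central data container: a tibble with an `area_id` column followed by
#' one numeric column per receptor, carrying a `units` attribute — either
#' `"fmol_per_mg_protein"` (raw autoradiography densities) or
#' `"fmol_per_neuron"` (densities normalised by neuron counts). All
#' densities must be non-negative and area ids unique.
#'
#' @param x A numeric matrix (rownames = area ids, colnames = receptors) or a
#'   data frame with an `area_id` column.
#' @param units `"fmol_per_mg_protein"` or `"fmol_per_neuron"`.
#' @return A `receptor_matrix` tibble.
#' @export
as_receptor_matrix <- function(x, units = c("fmol_per_mg_protein",
                                            "fmol_per_neuron")) {
  units <- match.arg(units)
  if (is.matrix(x)) {
    stopifnot(!is.null(rownames(x)), !is.null(colnames(x)))
    out <- tibble::as_tibble(x, rownames = "area_id")
  } else {
    stopifnot("area_id" %in% names(x))
    out <- tibble::as_tibble(x)
  }
  if (anyDuplicated(out$area_id)) stop("area ids must be unique")
  vals <- as.matrix(out[setdiff(names(out), "area_id")])
  if (any(!is.finite(vals))) stop("densities must be finite")
  if (any(vals < 0)) stop("densities must be non-negative")
  attr(out, "units") <- units
  class(out) <- c("receptor_matrix", class(out))
  out
}

#' @export
print.receptor_matrix <- function(x, ...) {
  cat("<receptor_matrix> units:", attr(x, "units"), "\n")
  NextMethod()
}

# Numeric matrix view (areas x receptors) of a receptor_matrix tibble.
rm_values <- function(rm) {
  m <- as.matrix(rm[setdiff(names(rm), "area_id")])
  rownames(m) <- rm$area_id
  m
}

rm_units <- function(rm) attr(rm, "units") %||% "fmol_per_mg_protein"

`%||%` <- function(a, b) if (is.null(a)) b else a
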