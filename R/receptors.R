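#' Canonical receptor panel
#'
#' The 14 neurotransmitter receptor types the analysis is built around, in
#' canonical order: glutamate (AMPA, kainate, NMDA), GABA (GABA_A, GABA_A/BZ,
#' GABA_B), acetylcholine (M1, M2, M3), serotonin (5-HT1A, 5-HT2A),
#' noradrenaline (alpha1, alpha2) and dopamine (D1). Fingerprints and
#' loading tables follow this order.
#'
#' @return Character vector of length 14.
#' @export
receptor_names <- function() {
  c("AMPA", "kainate", "NMDA",
    "GABAA", "GABAA_BZ", "GABAB",
    "M1", "M2", "M3",
    "5HT1A", "5HT2A",
    "alpha1", "alpha2",
    "D1")
}

# fmol receptor per mg protein <-> fmol per neuron conversion constants
.protein_fraction_default <- 0.08   # fraction of tissue mass that is protein
.mg_per_g <- 1000                   # mg protein per g tissue scale factor
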