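# Small truth specs used across test files.

# One enzyme at one depth with round-number kinetics.
tiny_truth <- function(vmax = 10, km = 200, rho = 0.5, sigma_f = 0,
                       depth = 4.5, seed = 1L, ...) {
  truth_spec(
    enzymes = tibble::tibble(
      enzyme = "clostripain", enzyme_class = "peptidase",
      substrate = "Z-Phe-Val-Arg-AMC", fluorophore = "AMC",
      depth_mbsf = depth, vmax_nmol_g_h = vmax, km_uM = km, rho = rho),
    calibration = tibble::tibble(fluorophore = "AMC", slope = 1000,
                                 intercept = 50),
    sigma_f = sigma_f, seed = seed, ...)
}

# A few enzymes over a few depths, all with the same retention fraction.
small_truth <- function(rho = 0.5, sigma_f = 2, seed = 1L,
                        depths = c(4.5, 11.1, 24.3, 48.22)) {
  base <- baltic_enzyme_truth(depths = depths)
  keep <- c("clostripain", "leucyl aminopeptidase", "beta-glucosidase",
            "alkaline phosphatase")
  base <- base[base$enzyme %in% keep & base$vmax_nmol_g_h > 0, ]
  base$rho <- rho
  truth_spec(enzymes = base, sigma_f = sigma_f, seed = seed)
}
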