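#' Assay geometry for sediment slurry incubations
#'
#' Describes how an enzyme assay cuvette is assembled: a slurry of
#' `sediment_g` grams of wet sediment in `slurry_ml` millilitres of
#' buffer, of which `reaction_ml` is incubated per cuvette after adding
#' substrate from a stock of `stock_mM`. The defaults follow the common
#' "thin slurry" protocol (3 g sediment in 100 ml buffer, 1 ml reactions,
#' 20 mM substrate stocks), chosen to minimise inhibition by humic
#' substances and maximise light transmission.
#'
#' @param sediment_g Wet sediment mass in the slurry (g).
#' @param slurry_ml Total slurry volume (ml).
#' @param reaction_ml Reaction (cuvette) volume (ml).
#' @param stock_mM Substrate stock concentration (mM).
#' @return An object of class `assay_geometry`.
#' @examples
#' geom <- assay_geometry()
#' grams_sediment_per_reaction(geom)  # 0.03 g
#' @export
assay_geometry <- function(sediment_g = 3, slurry_ml = 100,
                           reaction_ml = 1, stock_mM = 20) {
  vals <- c(sediment_g = sediment_g, slurry_ml = slurry_ml,
            reaction_ml = reaction_ml, stock_mM = stock_mM)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all assay geometry parameters must be finite and strictly positive",
         call. = FALSE)
  }
  structure(as.list(vals), class = "assay_geometry")
}

#' @export
print.assay_geometry <- function(x, ...) {
  cat(sprintf(
    "<assay_geometry> %g g sediment / %g ml slurry; %g ml reactions; %g mM stock\n",
    x$sediment_g, x$slurry_ml, x$reaction_ml, x$stock_mM))
  invisible(x)
}

#' Grams of sediment contained in one reaction volume
#'
#' @param geom An [assay_geometry()].
#' @return Sediment mass per cuvette (g).
#' @export
grams_sediment_per_reaction <- function(geom) {
  stopifnot(inherits(geom, "assay_geometry"))
  geom$sediment_g * geom$reaction_ml / geom$slurry_ml
}

#' Final substrate concentration after dilution into the reaction
#'
#' Computes the in-cuvette substrate concentration when `aliquot_ul` of a
#' `stock_mM` stock is made up to `total_ul` with sample slurry (plus
#' carrier solvent). With a 20 mM stock, 20 ul into 1000 ul gives the
#' standard 400 uM single-concentration design.
#'
#' @param stock_mM Stock concentration (mM).
#' @param aliquot_ul Stock volume added (ul); may be zero.
#' @param total_ul Final reaction volume (ul).
#' @return Final concentration in uM.
#' @examples
#' final_substrate_concentration(20, 20, 1000)  # 400 uM
#' @export
final_substrate_concentration <- function(stock_mM, aliquot_ul, total_ul) {
  if (!all(is.finite(c(stock_mM, aliquot_ul, total_ul)))) {
    stop("all arguments must be finite", call. = FALSE)
  }
  if (stock_mM <= 0 || total_ul <= 0 || any(aliquot_ul < 0)) {
    stop("stock and total volume must be positive; aliquot non-negative",
         call. = FALSE)
  }
  if (any(aliquot_ul > total_ul)) {
    stop("aliquot volume cannot exceed total reaction volume", call. = FALSE)
  }
  # mM * 1000 = uM, diluted by aliquot/total
  stock_mM * 1000 * aliquot_ul / total_ul
}

#' Convert a volumetric hydrolysis rate to a per-gram-sediment rate
#'
#' A rate measured in the cuvette in uM h^-1 (equivalently nmol ml^-1
#' h^-1) is converted to nmol per gram of wet sediment per hour: nmol
#' produced per hour in the reaction divided by the grams of sediment the
#' reaction contains. With the default geometry (0.03 g sediment per 1 ml
#' reaction) the factor is 100/3.
#'
#' @param v_uM_per_h Rate(s) in uM h^-1; vectorised.
#' @param geom An [assay_geometry()].
#' @return Rate(s) in nmol g^-1 h^-1.
#' @examples
#' convert_rate_units(0.3, assay_geometry())  # 10 nmol g^-1 h^-1
#' @export
convert_rate_units <- function(v_uM_per_h, geom = assay_geometry()) {
  stopifnot(inherits(geom, "assay_geometry"))
  v_uM_per_h * geom$reaction_ml / grams_sediment_per_reaction(geom)
}

#' Inverse of [convert_rate_units()]
#'
#' Maps a per-gram rate back to the volumetric rate it would produce in
#' the cuvette; used by the synthetic-data generator.
#'
#' @inheritParams convert_rate_units
#' @param v_nmol_g_h Rate(s) in nmol g^-1 h^-1.
#' @return Rate(s) in uM h^-1.
#' @export
rate_per_gram_to_uM <- function(v_nmol_g_h, geom = assay_geometry()) {
  stopifnot(inherits(geom, "assay_geometry"))
  v_nmol_g_h * grams_sediment_per_reaction(geom) / geom$reaction_ml
}
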