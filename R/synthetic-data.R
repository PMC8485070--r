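#' Reference table of assayed enzymes
#'
#' The twelve fluorogenic-substrate enzymes assayed in Baltic Sea Basin
#' sediments, with their class (`peptidase`, `glycosylase`,
#' `phosphatase`), substrate proxy, fluorophore (AMC for peptidase
#' substrates, MUB for glycosylase and phosphatase substrates) and EC
#' number (`na` where no formally described enzyme matches the substrate).
#'
#' @return A tibble with columns `enzyme`, `enzyme_class`, `description`,
#'   `substrate`, `fluorophore`, `ec`.
#' @export
enzyme_reference <- function() {
  path <- system.file("extdata", "enzyme_classes.csv", package = "sedenz",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Default depth grid for the synthetic study layout (mbsf)
#'
#' Eleven sampled horizons between 4.5 and 77.9 mbsf; the first eight lie
#' in the marine deposits above the unconformity at 51.7 mbsf, the last
#' three in the underlying lacustrine deposits.
#'
#' @return Numeric vector of depths in mbsf, ascending.
#' @export
baltic_depths <- function() {
  c(4.50, 11.10, 17.60, 24.30, 30.90, 37.50, 43.15, 48.22,
    54.95, 61.55, 77.92)
}

# Relative Vmax depth shapes per enzyme class, aligned with baltic_depths().
# Peptidases rise from the shallowest sample to a peak near 11 mbsf, decline
# to ~31 mbsf, recover slightly toward the unconformity, and vanish below
# it. Phosphatase declines roughly exponentially but stays detectable
# throughout. Most glycosylases show no signal; beta-glucosidase is active
# above ~30 mbsf only.
.depth_shapes <- function() {
  list(
    peptidase      = c(0.65, 1.00, 0.80, 0.55, 0.30, 0.38, 0.45, 0.50, 0, 0, 0),
    phosphatase    = c(1.00, 0.85, 0.70, 0.58, 0.47, 0.39, 0.32, 0.27,
                       0.10, 0.06, 0.028),
    `beta-glucosidase` = c(1.00, 0.80, 0.55, 0.35, 0.15, 0, 0, 0, 0, 0, 0),
    `alpha-glucosidase` = c(0, 0, 0, 0.10, 0, 0, 0, 0, 0, 0, 0),
    `N-acetyl-beta-glucosaminidase` = c(0.10, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    none           = rep(0, 11)
  )
}

#' Ground-truth kinetic parameters emulating the Baltic Sea study layout
#'
#' Builds the per-enzyme-per-depth truth table used by [truth_spec()]:
#' peak potential activities, Michaelis constants and autoclave-retention
#' fractions shaped like the field observations (peptidase activity
#' peaking near 11 mbsf and absent below the 51.7 mbsf unconformity,
#' phosphatase active throughout, most glycosylases silent).
#'
#' @param depths Depth grid (mbsf); defaults to [baltic_depths()].
#' @param unconformity_mbsf Depth below which all classes except
#'   phosphatase have zero true activity (default 51.7 mbsf).
#' @return A tibble with one row per enzyme x depth and columns `enzyme`,
#'   `enzyme_class`, `substrate`, `fluorophore`, `depth_mbsf`,
#'   `vmax_nmol_g_h`, `km_uM`, `rho`.
#' @export
baltic_enzyme_truth <- function(depths = baltic_depths(),
                                unconformity_mbsf = 51.7) {
  ref <- enzyme_reference()
  shapes <- .depth_shapes()
  # peak potential activities (nmol g-1 h-1), Km (uM; 300 where the
  # saturation curve gave no fit), and killed/live retention fractions
  pars <- tibble::tribble(
    ~enzyme,                          ~peak, ~km,  ~rho,
    "leucyl aminopeptidase",           10.0, 73.0, 0.151,
    "arginyl aminopeptidase",          12.0, 61.1, 0.300,
    "prolyl aminopeptidase",            7.3, 168,  0.350,
    "ornithyl aminopeptidase",          5.0, 997,  0.878,
    "gingipain",                       15.0, 69.5, 0.0987,
    "clostripain",                     22.2, 200,  0.0591,
    "beta-xylosidase",                  0.0, 300,  0.772,
    "beta-cellobiohydrolase",           0.0, 300,  0.772,
    "N-acetyl-beta-glucosaminidase",    2.0, 351,  0.772,
    "beta-glucosidase",                16.1, 230,  0.772,
    "alpha-glucosidase",                1.5, 300,  0.772,
    "alkaline phosphatase",            74.6, 1013, 0.540
  )
  grid <- tidyr::crossing(ref, depth_mbsf = sort(depths))
  grid <- dplyr::left_join(grid, pars, by = "enzyme")
  shape_of <- function(enzyme, class) {
    if (enzyme %in% names(shapes)) return(shapes[[enzyme]])
    if (class %in% names(shapes)) return(shapes[[class]])
    shapes$none
  }
  grid <- dplyr::group_by(grid, .data$enzyme)
  grid <- dplyr::mutate(
    grid,
    vmax_nmol_g_h = .data$peak *
      stats::approx(baltic_depths(),
                    shape_of(.data$enzyme[1], .data$enzyme_class[1]),
                    xout = .data$depth_mbsf, rule = 2)$y
  )
  grid <- dplyr::ungroup(grid)
  grid$vmax_nmol_g_h[grid$depth_mbsf > unconformity_mbsf &
                       grid$enzyme_class != "phosphatase"] <- 0
  dplyr::select(grid, "enzyme", "enzyme_class", "substrate", "fluorophore",
                "depth_mbsf", "vmax_nmol_g_h", km_uM = "km", "rho")
}

#' Ground-truth specification for the synthetic-data generator
#'
#' Bundles everything the generator needs to produce fluorescence time
#' series, standard curves and cell-count profiles with a known answer:
#' per-enzyme-per-depth kinetic truth, calibration lines per fluorophore,
#' fluorescence noise, replication, assay geometry and the segmented
#' cell-count model. All downstream estimators can then be tested by
#' parameter recovery.
#'
#' @param enzymes Truth table as produced by [baltic_enzyme_truth()]
#'   (columns `enzyme`, `enzyme_class`, `substrate`, `fluorophore`,
#'   `depth_mbsf`, `vmax_nmol_g_h`, `km_uM`, `rho`).
#' @param calibration Tibble with columns `fluorophore`, `slope`
#'   (fluorescence units per uM, > 0) and `intercept` (fluorescence
#'   units); one row per fluorophore in `enzymes`.
#' @param sigma_f Homoscedastic Gaussian fluorescence noise SD
#'   (fluorescence units, >= 0).
#' @param n_replicates Replicates per treatment (default 3).
#' @param n_timepoints Fluorescence readings per cuvette (3--5).
#' @param horizon_h Incubation horizon in hours (default 24).
#' @param unconformity_mbsf Depth of the stratigraphic unconformity
#'   separating the marine from the lacustrine deposits (default 51.7).
#' @param cells Segmented cell-count model: a list with elements `upper`
#'   and `lower`, each `list(ref_depth, log10_ref, slope)` giving a
#'   log10-linear decline anchored at a reference depth, plus
#'   `sigma_log10`, the lognormal count noise SD.
#' @param geometry An [assay_geometry()].
#' @param deep_classes Enzyme classes allowed nonzero activity below the
#'   unconformity (default `"phosphatase"`); any other class with deep
#'   activity in `enzymes` is an error.
#' @param seed Integer seed; identical specs generate byte-identical
#'   tables.
#' @return An object of class `truth_spec`.
#' @export
truth_spec <- function(enzymes = baltic_enzyme_truth(),
                       calibration = tibble::tibble(
                         fluorophore = c("AMC", "MUB"),
                         slope = c(1000, 1200),
                         intercept = c(50, 40)),
                       sigma_f = 5,
                       n_replicates = 3L,
                       n_timepoints = 4L,
                       horizon_h = 24,
                       unconformity_mbsf = 51.7,
                       cells = list(
                         upper = list(ref_depth = 4.35,
                                      log10_ref = log10(4.6e8),
                                      slope = -0.0105),
                         lower = list(ref_depth = 54.95,
                                      log10_ref = log10(9.0e7),
                                      slope = -0.0077),
                         sigma_log10 = 0.05),
                       geometry = assay_geometry(),
                       deep_classes = "phosphatase",
                       seed = 1L) {
  enzymes <- tibble::as_tibble(enzymes)
  req <- c("enzyme", "enzyme_class", "fluorophore", "depth_mbsf",
           "vmax_nmol_g_h", "km_uM", "rho")
  missing_cols <- setdiff(req, names(enzymes))
  if (length(missing_cols) > 0) {
    stop("truth table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(enzymes$vmax_nmol_g_h < 0)) stop("V_max must be >= 0", call. = FALSE)
  if (any(enzymes$km_uM <= 0)) stop("K_m must be > 0", call. = FALSE)
  if (any(enzymes$rho < 0)) stop("retention fraction rho must be >= 0",
                                 call. = FALSE)
  if (sigma_f < 0) stop("sigma_f must be >= 0", call. = FALSE)
  if (n_replicates < 1) stop("need at least one replicate", call. = FALSE)
  if (n_timepoints < 3 || n_timepoints > 5) {
    stop("n_timepoints must be between 3 and 5", call. = FALSE)
  }
  if (horizon_h <= 0) stop("assay horizon must be positive", call. = FALSE)
  bad_cal <- setdiff(unique(enzymes$fluorophore), calibration$fluorophore)
  if (length(bad_cal) > 0) {
    stop("no calibration parameters for fluorophore(s): ",
         paste(bad_cal, collapse = ", "), call. = FALSE)
  }
  if (any(calibration$slope <= 0)) {
    stop("calibration slopes must be positive", call. = FALSE)
  }
  deep <- enzymes$depth_mbsf > unconformity_mbsf &
    enzymes$vmax_nmol_g_h > 0 & !(enzymes$enzyme_class %in% deep_classes)
  if (any(deep)) {
    stop("nonzero V_max below the unconformity for class(es) not in ",
         "`deep_classes`: ",
         paste(unique(enzymes$enzyme_class[deep]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(enzymes = enzymes, calibration = calibration,
                 sigma_f = sigma_f, n_replicates = as.integer(n_replicates),
                 n_timepoints = as.integer(n_timepoints),
                 horizon_h = horizon_h,
                 unconformity_mbsf = unconformity_mbsf, cells = cells,
                 geometry = geometry, deep_classes = deep_classes,
                 seed = as.integer(seed)),
            class = "truth_spec")
}

#' @export
print.truth_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<truth_spec> %d enzymes x %d depths; sigma_F = %g; %d replicates; ",
    "%d timepoints over %g h; unconformity %g mbsf; seed %d\n"),
    length(unique(x$enzymes$enzyme)), length(unique(x$enzymes$depth_mbsf)),
    x$sigma_f, x$n_replicates, x$n_timepoints, x$horizon_h,
    x$unconformity_mbsf, x$seed))
  invisible(x)
}

# Product accumulated by t under substrate depletion (integrated
# Michaelis-Menten): P solves km*ln(s0/(s0-P)) + P = vmax*t.
integrated_mm_product <- function(vmax_uM_h, km_uM, s0_uM, t_h) {
  if (s0_uM <= 0 || vmax_uM_h <= 0) return(rep(0, length(t_h)))
  vapply(t_h, function(t) {
    if (t <= 0) return(0)
    f <- function(p) km_uM * log(s0_uM / (s0_uM - p)) + p - vmax_uM_h * t
    upper <- s0_uM * (1 - 1e-12)
    if (f(upper) < 0) return(upper)
    stats::uniroot(f, c(0, upper), tol = 1e-12)$root
  }, numeric(1))
}

#' Generate a synthetic fluorogenic assay dataset
#'
#' Simulates the cuvette fluorescence time series of a full assay
#' campaign from known ground truth. For every enzyme x depth x treatment
#' x replicate (x substrate concentration, for the saturation design) a
#' series `F(t) = b + m * P(t) + eps` is produced, where the product
#' concentration `P(t) = v(S) * t` accumulates linearly at the
#' Michaelis-Menten rate `v(S) = V_max S / (K_m + S)` (scaled by the
#' retention fraction `rho` for the autoclaved treatment), converted from
#' per-gram to cuvette concentration units via the assay geometry, and
#' `eps ~ N(0, sigma_F)`.
#'
#' Two designs are supported: `"vmax"` measures at the single saturating
#' concentration implied by the geometry's stock dilution (400 uM by
#' default), and `"saturation"` spans 11 evenly spaced concentrations from
#' 0 to 800 uM (overridable via `concentrations_uM`).
#'
#' @param truth A [truth_spec()].
#' @param design `"vmax"` (single concentration) or `"saturation"`.
#' @param depths,enzymes Optional subsets of the truth table.
#' @param concentrations_uM Optional explicit substrate levels (uM) for
#'   the saturation design.
#' @param depletion If `TRUE`, products accumulate under the integrated
#'   (substrate-depleting) rate law instead of linearly, to probe
#'   initial-rate estimation bias.
#' @param seed Seed; defaults to the spec's.
#' @return A list of class `assay_dataset` with elements `series` (a
#'   tibble in the canonical assay layout: `sample_id`, `depth_mbsf`,
#'   `enzyme`, `enzyme_class`, `substrate`, `fluorophore`, `treatment`,
#'   `replicate`, `substrate_conc_uM`, `time_h`, `fluorescence`) and
#'   `truth` (the spec, for recovery tests).
#' @export
generate_assay_dataset <- function(truth,
                                   design = c("vmax", "saturation"),
                                   depths = NULL, enzymes = NULL,
                                   concentrations_uM = NULL,
                                   depletion = FALSE,
                                   seed = truth$seed) {
  stopifnot(inherits(truth, "truth_spec"))
  design <- match.arg(design)
  if (truth$horizon_h <= 0) stop("assay horizon must be positive",
                                 call. = FALSE)
  geom <- truth$geometry
  tab <- truth$enzymes
  if (!is.null(depths)) tab <- dplyr::filter(tab, .data$depth_mbsf %in% depths)
  if (!is.null(enzymes)) tab <- dplyr::filter(tab, .data$enzyme %in% enzymes)
  if (nrow(tab) == 0) stop("no enzyme x depth cells selected", call. = FALSE)

  concs <- if (design == "vmax") {
    final_substrate_concentration(geom$stock_mM, 20, 1000)
  } else if (!is.null(concentrations_uM)) {
    sort(unique(concentrations_uM))
  } else {
    seq(0, 800, length.out = 11)
  }
  times <- seq(0, truth$horizon_h, length.out = truth$n_timepoints)

  set.seed(seed)
  grid <- tidyr::crossing(
    tab,
    treatment = c("live", "autoclaved"),
    replicate = seq_len(truth$n_replicates),
    substrate_conc_uM = concs,
    time_h = times)
  grid <- dplyr::arrange(grid, .data$enzyme, .data$depth_mbsf,
                         .data$treatment, .data$replicate,
                         .data$substrate_conc_uM, .data$time_h)
  grid <- dplyr::left_join(grid, truth$calibration, by = "fluorophore")

  v_g <- with(grid, vmax_nmol_g_h * substrate_conc_uM /
                (km_uM + substrate_conc_uM) *
                ifelse(treatment == "autoclaved", rho, 1))
  v_uM <- rate_per_gram_to_uM(v_g, geom)
  if (depletion) {
    key <- paste(v_uM, grid$km_uM, grid$substrate_conc_uM)
    p <- numeric(nrow(grid))
    for (k in unique(key)) {
      idx <- which(key == k)
      p[idx] <- integrated_mm_product(v_uM[idx[1]], grid$km_uM[idx[1]],
                                      grid$substrate_conc_uM[idx[1]],
                                      grid$time_h[idx])
    }
  } else {
    p <- v_uM * grid$time_h
  }
  grid$fluorescence <- grid$intercept + grid$slope * p +
    stats::rnorm(nrow(grid), 0, truth$sigma_f)
  series <- dplyr::transmute(
    grid,
    sample_id = sprintf("M0059C_%05.2f", .data$depth_mbsf),
    depth_mbsf = .data$depth_mbsf,
    enzyme = .data$enzyme, enzyme_class = .data$enzyme_class,
    substrate = .data$substrate, fluorophore = .data$fluorophore,
    treatment = .data$treatment, replicate = as.integer(.data$replicate),
    substrate_conc_uM = .data$substrate_conc_uM,
    time_h = .data$time_h, fluorescence = .data$fluorescence)
  structure(list(series = series, truth = truth, design = design),
            class = "assay_dataset")
}

#' @export
print.assay_dataset <- function(x, ...) {
  cat(sprintf("<assay_dataset> design '%s'; %d fluorescence readings\n",
              x$design, nrow(x$series)))
  invisible(x)
}

#' Generate synthetic standard-curve readings
#'
#' Simulates matrix-matched fluorophore standards: for each configured
#' fluorophore and each concentration level, `fluorescence = b + m*C +
#' eps` with `eps ~ N(0, sigma_F)`, replicated as in the spec.
#'
#' @param truth A [truth_spec()].
#' @param levels Standard concentrations (uM); at least 3 distinct
#'   non-negative values.
#' @param n_replicates Readings per level; defaults to the spec's.
#' @param seed Seed; defaults to the spec's.
#' @return Tibble with columns `fluorophore`, `concentration_uM`,
#'   `replicate`, `fluorescence`.
#' @export
generate_standard_curve_data <- function(truth,
                                         levels = c(0, 0.5, 1, 2, 4, 8),
                                         n_replicates = truth$n_replicates,
                                         seed = truth$seed) {
  stopifnot(inherits(truth, "truth_spec"))
  if (length(unique(levels)) < 3) {
    stop("need at least 3 distinct standard concentrations", call. = FALSE)
  }
  if (any(levels < 0)) stop("standard concentrations must be non-negative",
                            call. = FALSE)
  set.seed(seed)
  grid <- tidyr::crossing(truth$calibration,
                          concentration_uM = sort(unique(levels)),
                          replicate = seq_len(n_replicates))
  grid$fluorescence <- grid$intercept + grid$slope * grid$concentration_uM +
    stats::rnorm(nrow(grid), 0, truth$sigma_f)
  dplyr::select(grid, "fluorophore", "concentration_uM", "replicate",
                "fluorescence")
}

#' Generate synthetic cell-count data
#'
#' Cell abundances decline log10-linearly with depth, with independent
#' slope and anchor on either side of the unconformity and multiplicative
#' (lognormal) noise; all counts are positive.
#'
#' @param truth A [truth_spec()].
#' @param depths Depths (mbsf) at which to report counts; positive,
#'   ascending.
#' @param core Core label attached to the output rows.
#' @param seed Seed; defaults to the spec's.
#' @return Tibble with columns `core`, `depth_mbsf`, `cells_per_g`.
#' @export
generate_cell_counts <- function(truth, depths, core = "M0059C",
                                 seed = truth$seed) {
  stopifnot(inherits(truth, "truth_spec"))
  if (length(depths) == 0) stop("depth list is empty", call. = FALSE)
  if (any(depths <= 0)) stop("depths must be positive", call. = FALSE)
  if (is.unsorted(depths)) stop("depths must be sorted ascending",
                                call. = FALSE)
  cm <- truth$cells
  seg <- ifelse(depths <= truth$unconformity_mbsf, "upper", "lower")
  log10_mean <- vapply(seq_along(depths), function(i) {
    s <- cm[[seg[i]]]
    s$log10_ref + s$slope * (depths[i] - s$ref_depth)
  }, numeric(1))
  set.seed(seed)
  log10_obs <- log10_mean + stats::rnorm(length(depths), 0, cm$sigma_log10)
  tibble::tibble(core = core, depth_mbsf = depths,
                 cells_per_g = 10^log10_obs)
}

#' Generate a compilation of enzyme specific activities
#'
#' Draws `n` specific activities (mol bonds h^-1 per mol enzyme carbon)
#' from a [dist_spec()], emulating a literature compilation for the
#' lifetime model.
#'
#' @param n Number of values (>= 1).
#' @param dist A [dist_spec()]; log-scale families require positive
#'   parameters (enforced by the constructor).
#' @param seed Optional seed for reproducibility.
#' @return Numeric vector of `n` positive draws.
#' @export
generate_specific_activities <- function(n, dist, seed = NULL) {
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  draw_dist(as_dist_spec(dist), n)
}

#' Write an assay dataset to disk
#'
#' Writes the canonical assay CSV and a JSON sidecar holding the
#' generating truth (kinetic table, calibration, noise, geometry, seed)
#' so a run directory is self-describing.
#'
#' @param dataset An `assay_dataset` from [generate_assay_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_assay_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "assay_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "assay.csv")
  json <- file.path(dir, "truth.json")
  readr::write_csv(dataset$series, csv, progress = FALSE)
  truth <- dataset$truth
  truth$geometry <- unclass(truth$geometry)
  jsonlite::write_json(unclass(truth), json, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(assay = csv, truth = json))
}
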