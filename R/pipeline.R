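#' Default pipeline configuration
#'
#' Returns the full configuration list consumed by [run_pipeline()]:
#' assay geometry, detection-limit settings, exclusion and test levels,
#' cell-count interpolation degree, temperature scaling, and the lifetime
#' model's parameters. Any field can be overridden via a YAML config file
#' ([read_run_config()]) or by editing the list.
#'
#' @param outdir Output directory for all stage artifacts.
#' @param seed Integer seed controlling every stochastic stage.
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function(outdir = file.path(tempdir(), "sedenz_run"),
                               seed = 1L) {
  structure(list(
    outdir = outdir,
    seed = as.integer(seed),
    geometry = list(sediment_g = 3, slurry_ml = 100, reaction_ml = 1,
                    stock_mM = 20),
    unconformity_mbsf = 51.7,
    sigma_f = 5,
    detection = list(k = 3, override_live = NULL, override_killed = NULL),
    exclusion_k = 3,
    alpha = 0.05,
    poly_degree = 2,
    temperature = list(q10 = 2, assay_c = 20, insitu_c = 8),
    saturation = list(enzyme_multi_depth = "clostripain",
                      depths_multi = c(4.50, 11.10, 17.60, 24.30, 30.90,
                                       48.22)),
    cell_count_depths = sort(c(seq(2, 50, by = 4), seq(53, 80, by = 3))),
    lifetime = list(enzyme = "clostripain", depth_mbsf = 4.50,
                    sa = list(type = "log-uniform", lo = 1e2, hi = 1e4),
                    ge = 0.10, rc_nmol_cm3_day = 0.1, rho_s = 1, f_s = 1,
                    n_draws = 10000,
                    scenarios = list(conservative = list(f_s = 3,
                                                         ge = 0.037)))
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Loads a YAML file and merges it over [default_run_config()], so a
#' config file only needs to state the fields it changes.
#'
#' @param path Path to a YAML file.
#' @param outdir,seed Defaults passed to [default_run_config()]; values
#'   in the file win.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path, outdir = file.path(tempdir(),
                                                     "sedenz_run"),
                            seed = 1L) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  cfg <- merge_lists(unclass(default_run_config(outdir, seed)), user)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

# Internal: dist_spec from a config sub-list (type + parameters).
config_dist <- function(x) {
  if (is.numeric(x)) return(as_dist_spec(x))
  do.call(dist_spec, x)
}

#' Read and validate a canonical assay table
#'
#' Schema-validates a CSV in the canonical one-reading-per-row layout
#' (see [generate_assay_dataset()]): required columns present, treatments
#' in `{live, autoclaved}`, fluorophores in `{AMC, MUB}`, known enzyme
#' classes, non-negative times strictly increasing within each cuvette,
#' and no duplicated (sample, enzyme, treatment, replicate,
#' concentration, time) keys. Violations are reported with the offending
#' rows.
#'
#' @param path Path to an assay CSV.
#' @return A validated tibble.
#' @export
read_assay_table <- function(path) {
  if (!file.exists(path)) stop("assay file not found: ", path,
                               call. = FALSE)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("sample_id", "depth_mbsf", "enzyme", "enzyme_class", "substrate",
           "fluorophore", "treatment", "replicate", "substrate_conc_uM",
           "time_h", "fluorescence")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0) {
    stop(path, ": missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!tab$treatment %in% c("live", "autoclaved"))
  if (length(bad) > 0) {
    stop(path, ": invalid treatment at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (expected 'live' or 'autoclaved')", call. = FALSE)
  }
  bad <- which(!tab$fluorophore %in% c("AMC", "MUB"))
  if (length(bad) > 0) {
    stop(path, ": unknown fluorophore at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(!tab$enzyme_class %in% c("peptidase", "glycosylase",
                                        "phosphatase"))
  if (length(bad) > 0) {
    stop(path, ": unknown enzyme class at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (any(tab$time_h < 0)) stop(path, ": negative incubation times",
                                call. = FALSE)
  key <- paste(tab$sample_id, tab$enzyme, tab$treatment, tab$replicate,
               tab$substrate_conc_uM, tab$time_h, sep = "|")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop(path, ": duplicated series key at row(s) ",
         paste(utils::head(dup, 5), collapse = ", "),
         " (e.g. ", key[dup[1]], ")", call. = FALSE)
  }
  series_key <- paste(tab$sample_id, tab$enzyme, tab$treatment,
                      tab$replicate, tab$substrate_conc_uM, sep = "|")
  increasing <- tapply(tab$time_h, series_key,
                       function(t) all(diff(t) > 0))
  if (!all(increasing)) {
    stop(path, ": times not strictly increasing within series ",
         names(increasing)[which(!increasing)[1]], call. = FALSE)
  }
  tab
}

#' Read a cell-count CSV
#'
#' @param path CSV with columns `core`, `depth_mbsf`, `cells_per_g`.
#' @return A validated tibble.
#' @export
read_cell_counts <- function(path) {
  if (!file.exists(path)) stop("cell-count file not found: ", path,
                               call. = FALSE)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("depth_mbsf", "cells_per_g")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0) {
    stop(path, ": missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(tab$cells_per_g <= 0)) {
    stop(path, ": non-positive cell counts", call. = FALSE)
  }
  tab
}

# Internal: fail fast when a stage's input file is absent.
require_stage_input <- function(stage, path) {
  if (!file.exists(path)) {
    stop(sprintf("stage '%s': missing prerequisite %s (run the producing stage first or supply the file)",
                 stage, path), call. = FALSE)
  }
  path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in canonical order --
#' `simulate -> calibrate -> rates -> fit-mm -> profiles -> retention ->
#' lifetime` -- against a single output directory. Each stage reads its
#' inputs from files (written by an earlier stage or supplied by the
#' user) and writes CSV/JSON artifacts plus entries in a run manifest, so
#' reruns with the same config and inputs are idempotent and
#' byte-identical.
#'
#' Stage artifacts (in `config$outdir`): `assay_vmax.csv`,
#' `assay_saturation.csv`, `standards.csv`, `cell_counts.csv`,
#' `truth.json` (simulate); `standard_curves.csv` (calibrate);
#' `rates_vmax.csv`, `rates_saturation.csv` (rates); `mm_fits.csv`
#' (fit-mm); `depth_profile.csv` (profiles); `retention.csv`,
#' `retention_tests.json` (retention); `lifetime.csv` (lifetime); and
#' `manifest.json`.
#'
#' @param config A `run_config` (see [default_run_config()],
#'   [read_run_config()]).
#' @param stages Character subset of
#'   `c("simulate", "calibrate", "rates", "fit-mm", "profiles",
#'   "retention", "lifetime")`; executed in canonical order regardless of
#'   the order given.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = c("simulate", "calibrate", "rates",
                                    "fit-mm", "profiles", "retention",
                                    "lifetime"),
                         quiet = FALSE) {
  canonical <- c("simulate", "calibrate", "rates", "fit-mm", "profiles",
                 "retention", "lifetime")
  bad <- setdiff(stages, canonical)
  if (length(bad) > 0) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  stages <- canonical[canonical %in% stages]
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(outdir, f)
  geom <- do.call(assay_geometry, config$geometry)
  outputs <- list()
  warnings_log <- character()
  note <- function(msg) if (!quiet) message("[sedenz] ", msg)
  record <- function(name, path, n) {
    outputs[[name]] <<- list(path = basename(path), rows = n)
  }

  for (stage in stages) {
    switch(stage,
      "simulate" = {
        note("simulate: generating synthetic assay campaign")
        truth <- truth_spec(sigma_f = config$sigma_f, geometry = geom,
                            unconformity_mbsf = config$unconformity_mbsf,
                            seed = config$seed)
        vmax_ds <- generate_assay_dataset(truth, design = "vmax",
                                          seed = config$seed)
        sat_shallow <- generate_assay_dataset(
          truth, design = "saturation", depths = min(baltic_depths()),
          seed = config$seed + 1L)
        multi <- config$saturation
        sat_deep <- generate_assay_dataset(
          truth, design = "saturation",
          depths = setdiff(multi$depths_multi, min(baltic_depths())),
          enzymes = multi$enzyme_multi_depth, seed = config$seed + 2L)
        sat_series <- dplyr::bind_rows(sat_shallow$series, sat_deep$series)
        standards <- generate_standard_curve_data(truth,
                                                  seed = config$seed + 3L)
        cells <- generate_cell_counts(truth, config$cell_count_depths,
                                      seed = config$seed + 4L)
        readr::write_csv(vmax_ds$series, pth("assay_vmax.csv"),
                         progress = FALSE)
        readr::write_csv(sat_series, pth("assay_saturation.csv"),
                         progress = FALSE)
        readr::write_csv(standards, pth("standards.csv"), progress = FALSE)
        readr::write_csv(cells, pth("cell_counts.csv"), progress = FALSE)
        tj <- truth; tj$geometry <- unclass(tj$geometry)
        jsonlite::write_json(unclass(tj), pth("truth.json"),
                             auto_unbox = TRUE, digits = NA,
                             dataframe = "columns")
        record("assay_vmax", pth("assay_vmax.csv"), nrow(vmax_ds$series))
        record("assay_saturation", pth("assay_saturation.csv"),
               nrow(sat_series))
        record("standards", pth("standards.csv"), nrow(standards))
        record("cell_counts", pth("cell_counts.csv"), nrow(cells))
        record("truth", pth("truth.json"), nrow(truth$enzymes))
      },
      "calibrate" = {
        note("calibrate: fitting standard curves")
        std <- readr::read_csv(require_stage_input("calibrate",
                                                   pth("standards.csv")),
                               show_col_types = FALSE, progress = FALSE)
        curves <- fit_standard_curves(std)
        curve_tab <- purrr::map_dfr(curves, function(cv) {
          tibble::tibble(fluorophore = cv$fluorophore, slope = cv$slope,
                         intercept = cv$intercept, slope_se = cv$slope_se,
                         intercept_se = cv$intercept_se,
                         r_squared = cv$r_squared, sigma_f = cv$sigma_f,
                         n = cv$n)
        })
        readr::write_csv(curve_tab, pth("standard_curves.csv"),
                         progress = FALSE)
        record("standard_curves", pth("standard_curves.csv"),
               nrow(curve_tab))
      },
      "rates" = {
        note("rates: estimating v0 per cuvette")
        curves <- read_standard_curves(
          require_stage_input("rates", pth("standard_curves.csv")))
        for (design in c("vmax", "saturation")) {
          f_in <- pth(sprintf("assay_%s.csv", design))
          require_stage_input("rates", f_in)
          tab <- read_assay_table(f_in)
          rates <- estimate_rates(tab, curves, geom)
          f_out <- pth(sprintf("rates_%s.csv", design))
          readr::write_csv(rates, f_out, progress = FALSE)
          record(sprintf("rates_%s", design), f_out, nrow(rates))
        }
      },
      "fit-mm" = {
        note("fit-mm: fitting saturation curves")
        rates_sat <- readr::read_csv(
          require_stage_input("fit-mm", pth("rates_saturation.csv")),
          show_col_types = FALSE, progress = FALSE)
        fits <- fit_mm_from_rates(rates_sat)
        readr::write_csv(fits, pth("mm_fits.csv"), progress = FALSE)
        record("mm_fits", pth("mm_fits.csv"), nrow(fits))
        multi <- dplyr::filter(fits,
                               .data$enzyme ==
                                 config$saturation$enzyme_multi_depth,
                               .data$converged)
        if (nrow(multi) >= 3) {
          tr <- km_depth_trend(multi$depth_mbsf, multi$km)
          outputs[["km_depth_trend"]] <- tr
        }
      },
      "profiles" = {
        note("profiles: interpolating cell counts, assembling profiles")
        rates_vmax <- readr::read_csv(
          require_stage_input("profiles", pth("rates_vmax.csv")),
          show_col_types = FALSE, progress = FALSE)
        counts <- read_cell_counts(
          require_stage_input("profiles", pth("cell_counts.csv")))
        prof <- cell_count_profile(counts,
                                   unconformity_mbsf =
                                     config$unconformity_mbsf,
                                   degree = config$poly_degree)
        depths <- sort(unique(rates_vmax$depth_mbsf))
        cells_at <- tibble::tibble(
          depth_mbsf = depths,
          cells_per_g = interpolate_cell_counts(prof, depths))
        dl <- config$detection$override_live
        if (is.null(dl)) {
          curves <- read_standard_curves(
            require_stage_input("profiles", pth("standard_curves.csv")))
          dl <- detection_limit(sigma_f = config$sigma_f,
                                curve = curves[[1]],
                                horizon_h = 24,
                                k = config$detection$k, geom = geom)
        }
        table <- withCallingHandlers(
          assemble_depth_profile(rates_vmax, cells_at, dl = dl),
          warning = function(w) {
            warnings_log <<- c(warnings_log, conditionMessage(w))
            invokeRestart("muffleWarning")
          })
        readr::write_csv(table, pth("depth_profile.csv"), progress = FALSE)
        record("depth_profile", pth("depth_profile.csv"), nrow(table))
      },
      "retention" = {
        note("retention: retained-activity fractions and rank tests")
        profile <- readr::read_csv(
          require_stage_input("retention", pth("depth_profile.csv")),
          show_col_types = FALSE, progress = FALSE)
        dl <- unique(profile$detection_limit)[1]
        rec <- retention_table(profile, dl = dl,
                               exclusion_k = config$exclusion_k)
        readr::write_csv(rec, pth("retention.csv"), progress = FALSE)
        record("retention", pth("retention.csv"), nrow(rec))
        usable <- rec[!rec$excluded & is.finite(rec$fraction_pct), ]
        tests <- list(exclusion_k = config$exclusion_k,
                      detection_limit = dl, alpha = config$alpha)
        if (nrow(usable) >= 3 && length(unique(usable$enzyme_class)) >= 2) {
          grp <- split(usable$fraction_pct, usable$enzyme_class)
          kw <- kruskal_wallis(grp)
          ci <- conover_iman(grp, h = kw$H, alpha = config$alpha)
          tests$kruskal_wallis <- list(H = kw$H, df = kw$df, p = kw$p,
                                       n = kw$n)
          tests$conover_iman <- ci
          tests$summary_by_class <- summarize_retention(rec, by = "class")
          tests$summary_overall <- summarize_retention(rec, by = "all")
        }
        jsonlite::write_json(tests, pth("retention_tests.json"),
                             auto_unbox = TRUE, digits = NA,
                             dataframe = "rows")
        record("retention_tests", pth("retention_tests.json"),
               length(tests))
      },
      "lifetime" = {
        note("lifetime: Monte-Carlo turnover-time bounds")
        profile <- readr::read_csv(
          require_stage_input("lifetime", pth("depth_profile.csv")),
          show_col_types = FALSE, progress = FALSE)
        lt <- config$lifetime
        row <- dplyr::filter(profile, .data$enzyme == lt$enzyme,
                             .data$depth_mbsf == lt$depth_mbsf)
        if (nrow(row) != 1) {
          stop(sprintf("stage 'lifetime': no unique profile row for %s at %.2f mbsf",
                       lt$enzyme, lt$depth_mbsf), call. = FALSE)
        }
        inputs <- lifetime_inputs(
          vmax_nmol_g_h = row$live_v0,
          sa = config_dist(lt$sa), ge = config_dist(lt$ge),
          rc_nmol_cm3_day = config_dist(lt$rc_nmol_cm3_day),
          rho_s = lt$rho_s, f_s = lt$f_s, n_draws = lt$n_draws,
          seed = config$seed)
        tab <- sensitivity_table(inputs, lt$scenarios)
        tab$enzyme <- lt$enzyme
        tab$depth_mbsf <- lt$depth_mbsf
        tab$vmax_nmol_g_h <- row$live_v0
        readr::write_csv(tab, pth("lifetime.csv"), progress = FALSE)
        record("lifetime", pth("lifetime.csv"), nrow(tab))
      }
    )
  }

  manifest <- list(
    package = "sedenz",
    version = as.character(utils::packageVersion("sedenz")),
    seed = config$seed,
    stages = stages,
    config = unclass(config),
    # hash of the analysis settings only, so runs into different
    # directories with the same parameters share a fingerprint
    config_hash = rlang::hash(unclass(config)[setdiff(names(config),
                                                      "outdir")]),
    outputs = outputs,
    warnings = warnings_log)
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", dataframe = "rows")
  invisible(manifest)
}

#' Read standard curves written by the calibrate stage
#'
#' @param path `standard_curves.csv` as written by [run_pipeline()].
#' @return Named list of `standard_curve` objects keyed by fluorophore.
#' @export
read_standard_curves <- function(path) {
  if (!file.exists(path)) stop("standard-curve file not found: ", path,
                               call. = FALSE)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  curves <- lapply(seq_len(nrow(tab)), function(i) {
    structure(as.list(tab[i, c("fluorophore", "slope", "intercept",
                               "slope_se", "intercept_se", "r_squared",
                               "sigma_f", "n")]),
              class = "standard_curve")
  })
  names(curves) <- tab$fluorophore
  curves
}
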