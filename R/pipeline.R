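#' Run the full reverse-dosimetry analysis end to end
#'
#' Chains every stage of the analysis for rat and human: synthetic in vitro
#' AChE inhibition datasets are generated at the reference IC50s and fitted;
#' the PBK models are built from the reference in vitro metabolism
#' parameters; dose to unbound-Cmax maps are simulated; the in vitro
#' concentration-response curves are translated into in vivo dose-response
#' curves; benchmark doses (BMD10/BMDL10) are derived by model averaging; and
#' a local sensitivity profile is computed at each species' predicted BMDL10.
#' Optionally the rat urinary-excretion evaluation (BCP-glucuronide
#' sub-model) is run as well.
#'
#' All outputs are plain tibbles/lists; when `out_dir` is given they are also
#' written as CSV/JSON together with a run manifest (command, package
#' version, seed, timestamps, warnings) that makes every number
#' re-derivable. A stage failure aborts with the stage name.
#'
#' @param out_dir Optional output directory (created if missing).
#' @param seed Seed controlling every random stage (synthetic data,
#'   bootstrap).
#' @param n_boot Bootstrap replicates for the BMDL.
#' @param dose_grid Dose grid (mg/kg bw) for the Cmax maps.
#' @param conc_grid In vitro concentration grid (nM) translated into doses.
#' @param species Species to analyse.
#' @param evaluate_urinary Also run the rat urinary BCP-glucuronide
#'   evaluation (predicted vs synthetic observed excretion).
#' @param run_sensitivity Compute sensitivity profiles (the slowest stage).
#' @return A list: `ic50_fits`, `curves` (row-bound `dose_response_curve`s),
#'   `maps`, `bmd`, `sensitivity`, `urinary`, `manifest`.
#' @export
run_pipeline <- function(out_dir = NULL, seed = 20210302, n_boot = 200,
                         dose_grid = 10^seq(-4, 3, length.out = 40),
                         conc_grid = 10^seq(0, 5, by = 0.25),
                         species = c("rat", "human"),
                         evaluate_urinary = FALSE,
                         run_sensitivity = TRUE) {
  species <- match.arg(species, c("rat", "human"), several.ok = TRUE)
  t_start <- Sys.time()
  warnings <- character(0)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "revdosim_pipeline_error")
    })
    message(sprintf("[revdosim] %-24s %6.1f s", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  ref_ic50 <- profenofos_reference_ic50()
  ic50_fits <- stage("fit in vitro IC50s", {
    fits <- lapply(species, function(sp) {
      gen <- gen_inhibition_data(
        IC50 = ref_ic50$ic50_nM[ref_ic50$species == sp],
        noise = noise_model("additive", sd = 3, replicates = 3,
                            seed = seed + match(sp, c("rat", "human"))))
      fit_ic50(gen)
    })
    stats::setNames(fits, species)
  })

  models <- stage("build PBK models", {
    stats::setNames(lapply(species, function(sp) pbk_model(species = sp)), species)
  })

  maps <- stage("simulate Cmax maps", {
    stats::setNames(lapply(species, function(sp) {
      dose_to_cmax_map(models[[sp]], doses = dose_grid)
    }), species)
  })

  curves <- stage("reverse dosimetry", {
    stats::setNames(lapply(species, function(sp) {
      predict_dose_response(maps[[sp]], ic50_fits[[sp]], conc_grid = conc_grid)
    }), species)
  })

  bmd <- stage("BMD analysis", {
    stats::setNames(lapply(species, function(sp) {
      fits <- fit_dose_response_models(curves[[sp]])
      res <- model_average_bmdl(fits, curves[[sp]], bmr = 0.10,
                                n_boot = n_boot, seed = seed + 100)
      warnings <<- c(warnings, res$warnings)
      res
    }), species)
  })

  sens <- NULL
  if (run_sensitivity) {
    sens <- stage("sensitivity analysis", {
      stats::setNames(lapply(species, function(sp) {
        sensitivity_profile(models[[sp]], dose = bmd[[sp]]$bmdl)
      }), species)
    })
  }

  urinary <- NULL
  if (evaluate_urinary && "rat" %in% species) {
    urinary <- stage("urinary evaluation", {
      m <- pbk_model("rat", bcp = TRUE)
      predicted <- simulate_urinary_excretion(m, oral_dose = 35.8,
                                              duration = 120)
      observed <- gen_urinary_dataset(m, dose = 35.8,
                                      noise = noise_model("proportional",
                                                          cv = 0.1,
                                                          seed = seed + 7))
      list(predicted = predicted, observed_synthetic = observed)
    })
  }

  manifest <- list(
    command = "run_pipeline",
    package = "revdosim",
    version = as.character(utils::packageVersion("revdosim")),
    seed = seed,
    n_boot = n_boot,
    species = species,
    dose_grid_range = range(dose_grid),
    n_doses = length(dose_grid),
    conc_grid_range = range(conc_grid),
    started = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    warnings = warnings
  )

  result <- list(
    ic50_fits = ic50_fits,
    models = models,
    maps = maps,
    curves = dplyr::bind_rows(lapply(curves, tibble::as_tibble)),
    bmd = bmd,
    sensitivity = sens,
    urinary = urinary,
    manifest = manifest
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(result$curves,
                     file.path(out_dir, "dose_response_curves.csv"),
                     row.names = FALSE)
    for (sp in species) {
      utils::write.csv(tibble::as_tibble(maps[[sp]]),
                       file.path(out_dir, paste0("cmax_map_", sp, ".csv")),
                       row.names = FALSE)
      jsonlite::write_json(
        c(glance(bmd[[sp]]), list(models = tidy(bmd[[sp]]))),
        file.path(out_dir, paste0("bmd_", sp, ".json")),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
      if (run_sensitivity) {
        utils::write.csv(tibble::as_tibble(sens[[sp]]),
                         file.path(out_dir, paste0("sensitivity_", sp, ".csv")),
                         row.names = FALSE)
      }
    }
    if (!is.null(urinary)) {
      utils::write.csv(urinary$predicted,
                       file.path(out_dir, "urinary_predicted.csv"),
                       row.names = FALSE)
      utils::write.csv(urinary$observed_synthetic,
                       file.path(out_dir, "urinary_observed_synthetic.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  result
}
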