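#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

## The 14 anatomical compartments of the generic flow-limited model.
## "rest" is the lumped rest-of-body compartment.
PBK_COMPARTMENTS <- c(
  "liver", "gut", "fat", "muscle", "skin", "bone", "brain", "heart",
  "kidney", "lung", "spleen", "venous_blood", "arterial_blood", "rest"
)

## Tissues perfused directly from the arterial pool. The liver entry is the
## hepatic artery; gut and spleen outflows reach the liver via the portal vein.
PERFUSED_TISSUES <- c(
  "fat", "muscle", "skin", "bone", "brain", "heart", "kidney",
  "spleen", "gut", "liver", "rest"
)

#' Species physiology for the 14-compartment PBK model
#'
#' Constructs and validates the physiological parameter set (tissue volumes,
#' tissue blood flows, cardiac output, renal clearance) that parameterises one
#' species' flow-limited PBK model. Package-wide units: volumes L, flows L/h,
#' body weight kg.
#'
#' The compartment set is fixed: liver, gut (GI tract), fat, muscle, skin,
#' bone, brain, heart, kidney, lung, spleen, venous blood, arterial blood and
#' a rest-of-body compartment. `blood_flows` holds the arterial inflow of each
#' perfused tissue; the `liver` entry is the hepatic artery only (portal blood
#' from gut and spleen is added inside the model). The lung receives the full
#' cardiac output in series. The sum of tissue inflows must equal the cardiac
#' output within 1%.
#'
#' @param species_name `"rat"` or `"human"`.
#' @param body_weight Body weight (kg).
#' @param cardiac_output Cardiac output (L/h).
#' @param renal_clearance Passive renal (glomerular-filtration) clearance of
#'   unbound chemical in blood (L/h). Defaults used by the shipped configs are
#'   6.7 L/h (human) and 0.078 L/h (rat).
#' @param tissue_volumes Named numeric vector or list, one entry per
#'   compartment (L).
#' @param blood_flows Named numeric vector or list, one entry per perfused
#'   tissue (L/h).
#' @return An object of class `species_physiology` (a list with validated
#'   components; `tissues()`-style access via `$`).
#' @seealso [load_physiology()], [default_physiology()]
#' @export
species_physiology <- function(species_name, body_weight, cardiac_output,
                               renal_clearance, tissue_volumes, blood_flows) {
  species_name <- match.arg(species_name, c("rat", "human"))
  tissue_volumes <- unlist(tissue_volumes)
  blood_flows <- unlist(blood_flows)

  missing_v <- setdiff(PBK_COMPARTMENTS, names(tissue_volumes))
  if (length(missing_v) > 0) {
    abort(paste0("tissue_volumes is missing compartment(s): ",
                 paste(missing_v, collapse = ", ")),
          class = "revdosim_validation_error")
  }
  unknown_v <- setdiff(names(tissue_volumes), PBK_COMPARTMENTS)
  if (length(unknown_v) > 0) {
    abort(paste0("unknown tissue(s) in tissue_volumes: ",
                 paste(unknown_v, collapse = ", ")),
          class = "revdosim_validation_error")
  }
  missing_q <- setdiff(PERFUSED_TISSUES, names(blood_flows))
  if (length(missing_q) > 0) {
    abort(paste0("blood_flows is missing tissue(s): ",
                 paste(missing_q, collapse = ", ")),
          class = "revdosim_validation_error")
  }
  unknown_q <- setdiff(names(blood_flows), PERFUSED_TISSUES)
  if (length(unknown_q) > 0) {
    abort(paste0("unknown tissue(s) in blood_flows: ",
                 paste(unknown_q, collapse = ", ")),
          class = "revdosim_validation_error")
  }

  scalars <- c(body_weight = body_weight, cardiac_output = cardiac_output)
  bad <- names(scalars)[!is.finite(scalars) | scalars <= 0]
  if (length(bad) > 0) {
    abort(paste0("nonpositive or missing value for: ",
                 paste(bad, collapse = ", ")),
          class = "revdosim_validation_error")
  }
  ## renal clearance may legitimately be zero (e.g. limit-case analyses)
  if (!is.finite(renal_clearance) || renal_clearance < 0) {
    abort("renal_clearance must be >= 0", class = "revdosim_validation_error")
  }
  if (any(!is.finite(tissue_volumes) | tissue_volumes <= 0)) {
    bad <- names(tissue_volumes)[!is.finite(tissue_volumes) | tissue_volumes <= 0]
    abort(paste0("nonpositive tissue volume for: ", paste(bad, collapse = ", ")),
          class = "revdosim_validation_error")
  }
  if (any(!is.finite(blood_flows) | blood_flows <= 0)) {
    bad <- names(blood_flows)[!is.finite(blood_flows) | blood_flows <= 0]
    abort(paste0("nonpositive blood flow for: ", paste(bad, collapse = ", ")),
          class = "revdosim_validation_error")
  }

  ## flow balance: arterial outflow must equal venous return (= cardiac output)
  imbalance <- abs(sum(blood_flows) - cardiac_output) / cardiac_output
  if (imbalance > 0.01) {
    abort(sprintf(
      "sum of tissue blood flows (%.4g L/h) differs from cardiac output (%.4g L/h) by %.1f%% (> 1%%)",
      sum(blood_flows), cardiac_output, 100 * imbalance),
      class = "revdosim_validation_error")
  }

  structure(
    list(
      species_name = species_name,
      body_weight = unname(body_weight),
      cardiac_output = unname(cardiac_output),
      renal_clearance = unname(renal_clearance),
      tissue_volumes = tissue_volumes[PBK_COMPARTMENTS],
      blood_flows = blood_flows[PERFUSED_TISSUES]
    ),
    class = "species_physiology"
  )
}

#' @export
print.species_physiology <- function(x, ...) {
  cat(sprintf("<species_physiology> %s (%.3g kg)\n", x$species_name, x$body_weight))
  cat(sprintf("  cardiac output %.4g L/h, renal clearance %.4g L/h\n",
              x$cardiac_output, x$renal_clearance))
  cat(sprintf("  %d compartments, total tissue volume %.4g L\n",
              length(x$tissue_volumes), sum(x$tissue_volumes)))
  invisible(x)
}

#' Tidy view of a species physiology
#'
#' @param x A `species_physiology`.
#' @param ... Unused.
#' @return A tibble with one row per compartment: volume (L) and, for perfused
#'   tissues, arterial inflow (L/h).
#' @export
tidy.species_physiology <- function(x, ...) {
  tibble(
    species = x$species_name,
    tissue = names(x$tissue_volumes),
    volume_L = unname(x$tissue_volumes),
    flow_L_per_h = unname(x$blood_flows[names(x$tissue_volumes)])
  )
}

#' Load a species physiology from a structured config file
#'
#' Reads a YAML physiology config (see the packaged
#' `inst/extdata/physiology_rat.yaml` for the schema) and validates it with
#' [species_physiology()]. Missing compartments, unknown tissues, nonpositive
#' values and flow imbalance all raise validation errors naming the offending
#' field.
#'
#' @param config_source Path to a YAML file, or an already-parsed list with
#'   the same fields.
#' @return A validated `species_physiology`.
#' @export
load_physiology <- function(config_source) {
  cfg <- if (is.character(config_source)) yaml::read_yaml(config_source) else config_source
  needed <- c("species_name", "body_weight", "cardiac_output",
              "renal_clearance", "tissue_volumes", "blood_flows")
  missing <- setdiff(needed, names(cfg))
  if (length(missing) > 0) {
    abort(paste0("physiology config is missing field(s): ",
                 paste(missing, collapse = ", ")),
          class = "revdosim_validation_error")
  }
  species_physiology(
    species_name = cfg$species_name,
    body_weight = cfg$body_weight,
    cardiac_output = cfg$cardiac_output,
    renal_clearance = cfg$renal_clearance,
    tissue_volumes = cfg$tissue_volumes,
    blood_flows = cfg$blood_flows
  )
}

#' Write a species physiology back to a YAML config
#'
#' Round-trips exactly: `load_physiology(write_physiology(x, f))` reproduces
#' `x`.
#'
#' @param x A `species_physiology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_physiology <- function(x, path) {
  stopifnot(inherits(x, "species_physiology"))
  yaml::write_yaml(
    list(
      species_name = x$species_name,
      body_weight = x$body_weight,
      cardiac_output = x$cardiac_output,
      renal_clearance = x$renal_clearance,
      tissue_volumes = as.list(x$tissue_volumes),
      blood_flows = as.list(x$blood_flows)
    ),
    path, precision = 15
  )
  invisible(path)
}

#' Packaged default physiologies
#'
#' Returns the shipped reference physiology for a species. Values are
#' transcribed from the standard reference-compendium lineage (Jones &
#' Rowland-Yeo; Brown et al.) and are user-overridable by editing a copy of
#' the packaged YAML (see [load_physiology()]).
#'
#' @param species `"rat"` or `"human"`.
#' @return A `species_physiology`.
#' @export
default_physiology <- function(species = c("rat", "human")) {
  species <- match.arg(species)
  load_physiology(system.file("extdata",
                              paste0("physiology_", species, ".yaml"),
                              package = "revdosim", mustWork = TRUE))
}

#' Chemical properties used by partitioning and the PBK model
#'
#' @param name Chemical label.
#' @param molecular_weight Molecular weight (g/mol), > 0.
#' @param logKow Octanol:water log partition coefficient.
#' @param pKa Acid/base dissociation constant, or `NA` for a compound with no
#'   ionizable group in the physiological range.
#' @param ionization `"neutral"`, `"acid"` or `"base"`.
#' @param fup Fraction unbound in plasma, in (0, 1].
#' @param blood_plasma_ratio Blood:plasma concentration ratio. Defaults to 1:
#'   model "blood" concentrations are then plasma-equivalent, which is how
#'   predictions are reported throughout the package.
#' @return An object of class `chemical_properties`.
#' @export
chemical_properties <- function(name, molecular_weight, logKow, pKa = NA_real_,
                                ionization = c("neutral", "acid", "base"),
                                fup, blood_plasma_ratio = 1) {
  ionization <- match.arg(ionization)
  if (!is.finite(molecular_weight) || molecular_weight <= 0) {
    abort("molecular_weight must be > 0", class = "revdosim_validation_error")
  }
  if (!is.finite(fup) || fup <= 0 || fup > 1) {
    abort("fup must lie in (0, 1]", class = "revdosim_validation_error")
  }
  if (!is.finite(logKow)) {
    abort("logKow must be a finite number", class = "revdosim_validation_error")
  }
  if (ionization != "neutral" && !is.finite(pKa)) {
    abort("pKa is required for acid/base ionization classes",
          class = "revdosim_validation_error")
  }
  if (!is.finite(blood_plasma_ratio) || blood_plasma_ratio <= 0) {
    abort("blood_plasma_ratio must be > 0", class = "revdosim_validation_error")
  }
  structure(
    list(name = name, molecular_weight = molecular_weight, logKow = logKow,
         pKa = if (is.null(pKa)) NA_real_ else pKa,
         ionization = ionization, fup = fup,
         blood_plasma_ratio = blood_plasma_ratio),
    class = "chemical_properties"
  )
}

#' @export
print.chemical_properties <- function(x, ...) {
  cat(sprintf("<chemical_properties> %s: MW %.4g g/mol, logKow %.3g, %s, fup %.3g\n",
              x$name, x$molecular_weight, x$logKow, x$ionization, x$fup))
  invisible(x)
}

#' Load chemical properties from a structured config file
#'
#' @param config_source Path to a YAML file or an already-parsed list. See the
#'   shipped `chemical_profenofos.yaml` for the schema; that file also
#'   documents which defaults are literature-sourced rather than measured.
#' @return A validated `chemical_properties`. Any `partition_overrides` block
#'   in the file is attached as the `"partition_overrides"` attribute and
#'   honoured by [resolve_partitions()].
#' @export
load_chemical <- function(config_source) {
  cfg <- if (is.character(config_source)) yaml::read_yaml(config_source) else config_source
  needed <- c("name", "molecular_weight", "logKow", "fup")
  missing <- setdiff(needed, names(cfg))
  if (length(missing) > 0) {
    abort(paste0("chemical config is missing field(s): ",
                 paste(missing, collapse = ", ")),
          class = "revdosim_validation_error")
  }
  chem <- chemical_properties(
    name = cfg$name,
    molecular_weight = cfg$molecular_weight,
    logKow = cfg$logKow,
    pKa = if (is.null(cfg$pKa) || is.na(cfg$pKa)) NA_real_ else as.numeric(cfg$pKa),
    ionization = cfg$ionization %||% "neutral",
    fup = cfg$fup,
    blood_plasma_ratio = cfg$blood_plasma_ratio %||% 1
  )
  if (!is.null(cfg$partition_overrides)) {
    attr(chem, "partition_overrides") <- unlist(cfg$partition_overrides)
  }
  chem
}

#' Packaged chemical property defaults
#'
#' `default_chemical("profenofos")` returns the parent organophosphate;
#' `default_chemical("bcp")` returns 4-bromo-2-chlorophenol, its hydrolysis
#' product used by the rat evaluation sub-model. See the YAML headers under
#' `inst/extdata/` for the provenance of each value (several are
#' literature-sourced estimates rather than measured numbers).
#'
#' @param name `"profenofos"` or `"bcp"`.
#' @return A `chemical_properties`.
#' @export
default_chemical <- function(name = c("profenofos", "bcp")) {
  name <- match.arg(name)
  load_chemical(system.file("extdata", paste0("chemical_", name, ".yaml"),
                            package = "revdosim", mustWork = TRUE))
}
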