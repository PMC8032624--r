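# Shared fixtures built in code. Simulation helpers use coarse output grids
# where the quantity under test does not need peak-resolution accuracy.

quick_sim <- function(model, dose, hours = 24, n_out = 200, ...) {
  simulate_pbk(model, dose, hours = hours, n_out = n_out, ...)
}

quick_map <- function(model, doses = 10^seq(-2, 3, length.out = 12), ...) {
  dose_to_cmax_map(model, doses = doses, n_out = 200, ...)
}

# Physiology with a single scalar field replaced (revalidated on build).
physiology_with <- function(base, ...) {
  args <- list(...)
  spec <- list(
    species_name = base$species_name,
    body_weight = base$body_weight,
    cardiac_output = base$cardiac_output,
    renal_clearance = base$renal_clearance,
    tissue_volumes = base$tissue_volumes,
    blood_flows = base$blood_flows
  )
  spec[names(args)] <- args
  do.call(species_physiology, spec)
}

# Metabolism term table with all capacities zeroed (elimination-free model).
zero_kinetics <- function(species) {
  kin <- profenofos_invitro_kinetics()
  kin <- kin[kin$species == species, ]
  kin$Vmax_nmol_min_mg <- 0
  kin
}

elimination_free_model <- function(species = "rat") {
  phys <- physiology_with(default_physiology(species), renal_clearance = 0)
  pbk_model(species, physiology = phys,
            metabolism = build_metabolism(species, kinetics = zero_kinetics(species)))
}
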