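#' Assemble scaled metabolism terms for the PBK model
#'
#' Converts in vitro Michaelis-Menten parameters (per mg protein) into the
#' whole-organ capacities used by the model: liver-microsomal and
#' liver-cytosolic Vmax in umol/h/kg liver, plasma-enzyme Vmax in umol/h/kg
#' blood (via [scale_vmax_to_in_vivo()]). In vivo Km values equal the in
#' vitro values multiplied by the fraction unbound in the incubation
#' (`fumic`/`fucyt`/`fupla`, default 1), and the resulting Km is interpreted
#' on the unbound-concentration scale.
#'
#' @param species `"rat"` or `"human"`; selects rows of
#'   [profenofos_invitro_kinetics()] when `kinetics` is not supplied.
#' @param kinetics Optional tibble with columns `matrix`, `Km_uM`,
#'   `Vmax_nmol_min_mg` (e.g. from [fit_michaelis_menten()] results).
#' @param sf A [scaling_factors()] object.
#' @return A `pbk_metabolism` list with elements `mic`, `cyt`, `pla` (each
#'   `vmax` umol/h/kg, `km` uM) and the incubation unbound fractions.
#' @export
build_metabolism <- function(species = c("rat", "human"), kinetics = NULL,
                             sf = scaling_factors()) {
  species <- match.arg(species)
  if (is.null(kinetics)) {
    kin <- profenofos_invitro_kinetics()
    kinetics <- kin[kin$species == species, ]
  }
  get_row <- function(m) {
    row <- kinetics[kinetics$matrix == m, ]
    if (nrow(row) != 1) {
      abort(paste0("kinetics must contain exactly one row for matrix '", m, "'"),
            class = "revdosim_validation_error")
    }
    row
  }
  term <- function(m, fu_inc) {
    row <- get_row(m)
    if (row$Vmax_nmol_min_mg < 0 || row$Km_uM <= 0) {
      abort("metabolism requires Vmax >= 0 and Km > 0",
            class = "revdosim_validation_error")
    }
    list(vmax = scale_vmax_to_in_vivo(row$Vmax_nmol_min_mg, m, sf),
         km = row$Km_uM * fu_inc)
  }
  structure(
    list(
      mic = term("liver microsomes", sf$fumic),
      cyt = term("liver cytosol", sf$fucyt),
      pla = term("plasma", sf$fupla),
      fumic = sf$fumic, fucyt = sf$fucyt, fupla = sf$fupla
    ),
    class = "pbk_metabolism"
  )
}

## Default glucuronidation kinetics for the BCP sub-model: synthetic
## approximations of published rat-liver phenol glucuronidation parameters
## (per mg microsomal protein, scaled like the microsomal pathway).
## Configurable through pbk_model(bcp_options = ...).
default_bcp_options <- function(sf = scaling_factors()) {
  list(
    chem = default_chemical("bcp"),
    glucuronidation = list(
      vmax = scale_vmax_to_in_vivo(7.4, "liver microsomes", sf),  # umol/h/kg liver
      km = 400                                                    # uM, unbound
    ),
    fup_glucuronide = 0.9
  )
}

#' Build a 14-compartment flow-limited PBK model
#'
#' Assembles the full model specification for one species: first-order gut
#' lumen absorption (rate `ka`, absorbed flux routed entirely to the liver
#' via the portal vein), flow-limited tissue distribution
#' `Q_T (C_art - C_T / Kp_T)` for every tissue, lung in series with the full
#' cardiac output, saturable liver metabolism (microsomal + cytosolic
#' Michaelis-Menten acting on the unbound liver concentration), saturable
#' plasma-enzyme metabolism in the venous and arterial blood compartments
#' (split by volume), and passive renal clearance of the unbound venous-blood
#' concentration at the fixed species rate.
#'
#' With `bcp = TRUE` (rat evaluation sub-model) every mole of parent
#' metabolised forms one mole of the phenol metabolite (BCP), which
#' distributes over the same compartments with its own partition
#' coefficients, is glucuronidated in the liver (saturable, acting on unbound
#' BCP), and the glucuronide is held in a central blood compartment and
#' cleared to urine by glomerular filtration of its unbound fraction.
#'
#' @param species `"rat"` or `"human"`.
#' @param physiology A [species_physiology()]; defaults to the packaged one.
#' @param chem A [chemical_properties()]; defaults to profenofos.
#' @param partitions Partition tibble from [resolve_partitions()]; estimated
#'   from tissue composition when omitted. Every compartment must have a Kp.
#' @param metabolism A [build_metabolism()] result.
#' @param ka First-order absorption rate constant (1/h), default 1.
#' @param bcp Enable the BCP/BCP-glucuronide sub-model (rat only).
#' @param bcp_options Overrides for the sub-model: `chem`, `partitions`,
#'   `glucuronidation = list(vmax, km)`, `fup_glucuronide`.
#' @return A `pbk_model` object.
#' @export
pbk_model <- function(species = c("rat", "human"),
                      physiology = default_physiology(species),
                      chem = default_chemical("profenofos"),
                      partitions = NULL,
                      metabolism = build_metabolism(species),
                      ka = 1,
                      bcp = FALSE,
                      bcp_options = NULL) {
  species <- match.arg(species)
  stopifnot(inherits(physiology, "species_physiology"),
            inherits(chem, "chemical_properties"))
  if (!is.finite(ka) || ka <= 0) {
    abort("ka must be > 0", class = "revdosim_validation_error")
  }
  if (is.null(partitions)) {
    partitions <- resolve_partitions(chem = chem)
  }
  kp <- partition_vector(partitions)

  if (bcp && species != "rat") {
    abort("the BCP evaluation sub-model is defined for the rat model only",
          class = "revdosim_validation_error")
  }
  bcp_spec <- NULL
  if (bcp) {
    opts <- utils::modifyList(default_bcp_options(), bcp_options %||% list())
    bcp_partitions <- opts$partitions %||% resolve_partitions(chem = opts$chem)
    bcp_spec <- list(
      chem = opts$chem,
      kp = partition_vector(bcp_partitions),
      glucuronidation = opts$glucuronidation,
      fup_glucuronide = opts$fup_glucuronide
    )
  }

  structure(
    list(
      species = species,
      physiology = physiology,
      chem = chem,
      partitions = partitions,
      kp = kp,
      metabolism = metabolism,
      ka = ka,
      bcp = bcp_spec
    ),
    class = "pbk_model"
  )
}

#' @export
print.pbk_model <- function(x, ...) {
  cat(sprintf("<pbk_model> %s, %s (%.3g kg), ka = %.3g 1/h%s\n",
              x$chem$name, x$species, x$physiology$body_weight, x$ka,
              if (!is.null(x$bcp)) ", BCP sub-model on" else ""))
  invisible(x)
}

## ---------------------------------------------------------------------------
## internal: state layout and right-hand side

pbk_state_names <- function(model) {
  nm <- c("lumen", PBK_COMPARTMENTS, "urine", "amet")
  if (!is.null(model$bcp)) {
    nm <- c(nm, paste0("bcp_", PBK_COMPARTMENTS), "bcp_glu", "bcp_glu_urine")
  }
  nm
}

## Builds a closure computing the ODE right-hand side with integer indexing.
## Amounts umol, concentrations uM, time h.
pbk_rhs <- function(model) {
  ph <- model$physiology
  V <- unname(ph$tissue_volumes)            # aligned with PBK_COMPARTMENTS
  Q <- ph$blood_flows
  kp <- unname(model$kp)
  co <- ph$cardiac_output
  clr <- ph$renal_clearance
  fup <- model$chem$fup
  met <- model$metabolism
  ka <- model$ka

  ci <- function(x) match(x, PBK_COMPARTMENTS)
  i_li <- ci("liver"); i_gu <- ci("gut"); i_sp <- ci("spleen")
  i_lu <- ci("lung"); i_ve <- ci("venous_blood"); i_ar <- ci("arterial_blood")
  simple <- ci(c("fat", "muscle", "skin", "bone", "brain", "heart", "kidney", "rest"))
  Qsimple <- unname(Q[c("fat", "muscle", "skin", "bone", "brain", "heart",
                        "kidney", "rest")])
  Qha <- unname(Q["liver"]); Qgu <- unname(Q["gut"]); Qsp <- unname(Q["spleen"])
  Qli <- Qha + Qgu + Qsp

  ## liver and blood masses in kg (density 1 kg/L)
  m_li <- V[i_li]; m_ve <- V[i_ve]; m_ar <- V[i_ar]

  n_parent <- 1 + 14 + 2
  has_bcp <- !is.null(model$bcp)
  if (has_bcp) {
    bkp <- unname(model$bcp$kp)
    bfup <- model$bcp$chem$fup
    glu <- model$bcp$glucuronidation
    fug <- model$bcp$fup_glucuronide
    v_blood <- V[i_ve] + V[i_ar]
  }

  function(t, y, parms) {
    d <- numeric(length(y))
    A <- y[2:15]                 # compartment amounts, PBK_COMPARTMENTS order
    C <- A / V                   # total concentrations, uM
    Ca <- C[i_ar]; Cv <- C[i_ve]

    ## absorption
    d[1] <- -ka * y[1]

    ## simple flow-limited tissues
    Cout_simple <- C[simple] / kp[simple]
    d[1 + simple] <- Qsimple * (Ca - Cout_simple)

    ## splanchnic tissues draining to the portal vein
    Cout_gu <- C[i_gu] / kp[i_gu]
    Cout_sp <- C[i_sp] / kp[i_sp]
    d[1 + i_gu] <- Qgu * (Ca - Cout_gu)
    d[1 + i_sp] <- Qsp * (Ca - Cout_sp)

    ## liver: hepatic artery + portal vein + absorbed flux - outflow - metabolism
    Cout_li <- C[i_li] / kp[i_li]
    Cu_li <- fup * Cout_li
    met_li <- m_li * (met$mic$vmax * Cu_li / (met$mic$km + Cu_li) +
                        met$cyt$vmax * Cu_li / (met$cyt$km + Cu_li))
    d[1 + i_li] <- Qha * Ca + Qgu * Cout_gu + Qsp * Cout_sp + ka * y[1] -
      Qli * Cout_li - met_li

    ## blood-borne (plasma-enzyme) metabolism, split over venous and arterial
    Cu_v <- fup * Cv; Cu_a <- fup * Ca
    met_v <- m_ve * met$pla$vmax * Cu_v / (met$pla$km + Cu_v)
    met_a <- m_ar * met$pla$vmax * Cu_a / (met$pla$km + Cu_a)

    ## renal clearance of the unbound venous-blood concentration
    renal <- clr * Cu_v

    ## venous pool: tissue outflows in, lung out
    d[1 + i_ve] <- sum(Qsimple * Cout_simple) + Qli * Cout_li -
      co * Cv - met_v - renal

    ## lung in series with the full cardiac output
    Cout_lu <- C[i_lu] / kp[i_lu]
    d[1 + i_lu] <- co * (Cv - Cout_lu)
    d[1 + i_ar] <- co * Cout_lu - Ca * (sum(Qsimple) + Qgu + Qsp + Qha) - met_a

    d[16] <- renal                      # cumulative urine (parent)
    d[17] <- met_li + met_v + met_a     # cumulative parent metabolised

    if (has_bcp) {
      off <- n_parent
      B <- y[(off + 1):(off + 14)]
      Cb <- B / V
      Cba <- Cb[i_ar]; Cbv <- Cb[i_ve]
      bout_simple <- Cb[simple] / bkp[simple]
      d[off + simple] <- Qsimple * (Cba - bout_simple)
      bout_gu <- Cb[i_gu] / bkp[i_gu]; bout_sp <- Cb[i_sp] / bkp[i_sp]
      d[off + i_gu] <- Qgu * (Cba - bout_gu)
      d[off + i_sp] <- Qsp * (Cba - bout_sp)
      bout_li <- Cb[i_li] / bkp[i_li]
      Cu_bli <- bfup * bout_li
      gluc <- m_li * glu$vmax * Cu_bli / (glu$km + Cu_bli)
      ## BCP formed mole-for-mole where the parent is metabolised
      d[off + i_li] <- Qha * Cba + Qgu * bout_gu + Qsp * bout_sp -
        Qli * bout_li - gluc + met_li
      d[off + i_ve] <- sum(Qsimple * bout_simple) + Qli * bout_li -
        co * Cbv + met_v
      bout_lu <- Cb[i_lu] / bkp[i_lu]
      d[off + i_lu] <- co * (Cbv - bout_lu)
      d[off + i_ar] <- co * bout_lu - Cba * (sum(Qsimple) + Qgu + Qsp + Qha) +
        met_a
      ## glucuronide: central blood pool, renal filtration of unbound fraction
      C_glu <- y[off + 15] / v_blood
      glu_renal <- clr * fug * C_glu
      d[off + 15] <- gluc - glu_renal
      d[off + 16] <- glu_renal
    }

    list(d)
  }
}

## ---------------------------------------------------------------------------

#' Simulate the PBK model after a single oral dose
#'
#' Integrates the model ODEs with a stiff solver (deSolve; `lsoda` by
#' default, tolerances rtol 1e-8 / atol 1e-10). The oral dose enters the gut
#' lumen as a bolus at t = 0 and is converted to umol via the molecular
#' weight and body weight. Mass balance (body + lumen + eliminated vs dose)
#' is verified at every output time and must hold within 0.1%.
#'
#' @param model A [pbk_model()].
#' @param oral_dose Oral dose, mg/kg body weight (>= 0).
#' @param hours Simulation horizon (h); 24 h is the default for Cmax after a
#'   single dose, 120 h is typical for urinary-excretion evaluation.
#' @param n_out Number of output points (peak refinement interpolates between
#'   them).
#' @param rtol,atol Solver tolerances.
#' @param method deSolve integration method (stiff solvers recommended).
#' @return A `pbk_simulation`: time grid, amount matrix (umol), derived dose
#'   metrics (`cmax_venous_uM`, `cmax_unbound_uM`, `auc_uM_h`,
#'   `mass_balance` range) and the model. [tidy()] gives the long
#'   time-by-compartment table.
#' @export
simulate_pbk <- function(model, oral_dose, hours = 24, n_out = 400,
                         rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  stopifnot(inherits(model, "pbk_model"))
  if (!is.finite(oral_dose) || oral_dose < 0) {
    abort("oral_dose must be >= 0", class = "revdosim_validation_error")
  }
  if (!is.finite(hours) || hours <= 0) {
    abort("duration must be > 0", class = "revdosim_validation_error")
  }
  nm <- pbk_state_names(model)
  y0 <- stats::setNames(numeric(length(nm)), nm)
  dose_umol <- oral_dose * model$physiology$body_weight /
    model$chem$molecular_weight * 1000
  y0["lumen"] <- dose_umol

  ## two-phase output grid: the blood peak falls early in the absorption
  ## window, so spend most output points there and coarsen the tail
  early <- min(4 / model$ka, hours / 2)
  n_early <- ceiling(0.65 * n_out)
  times <- unique(c(seq(0, early, length.out = n_early),
                    seq(early, hours, length.out = n_out - n_early + 1)))
  rhs <- pbk_rhs(model)
  solve_on <- function(tt) {
    out <- tryCatch(
      deSolve::ode(y = y0, times = tt, func = rhs, parms = NULL,
                   method = method, rtol = rtol, atol = atol),
      error = function(e) abort(paste0("PBK solver failure: ",
                                       conditionMessage(e)),
                                class = "revdosim_solver_error")
    )
    if (attr(out, "istate")[1] < 0) {
      abort(sprintf(
        "PBK solver failure (istate %d) at t ~ %.3g h; final state range [%.3g, %.3g]",
        attr(out, "istate")[1], max(out[, "time"]),
        min(out[nrow(out), -1]), max(out[nrow(out), -1])),
        class = "revdosim_solver_error")
    }
    out
  }
  out <- solve_on(times)
  ## the venous peak can be much sharper than the output grid: locate it
  ## coarsely, then re-solve with a dense window around it
  if (dose_umol > 0) {
    i_ven <- which(nm == "venous_blood")
    cv0 <- out[, 1 + i_ven]
    ipk <- which.max(cv0)
    dt_loc <- max(diff(times[max(ipk - 1, 1):min(ipk + 1, length(times))]))
    t_lo <- max(0, times[ipk] - 2 * dt_loc)
    t_hi <- min(hours, times[ipk] + 2 * dt_loc)
    window <- seq(t_lo, t_hi, length.out = 120)
    times <- sort(unique(c(times, window)))
    out <- solve_on(times)
  }
  amounts <- out[, nm, drop = FALSE]

  ## mass balance: everything that entered must be accounted for
  balance_cols <- if (is.null(model$bcp)) nm else setdiff(nm, "amet")
  total <- rowSums(amounts[, balance_cols, drop = FALSE])
  if (dose_umol > 0) {
    mb <- total / dose_umol
    if (any(mb < 0.999 | mb > 1.001)) {
      abort(sprintf("mass balance violated: range [%.6f, %.6f] of dose",
                    min(mb), max(mb)),
            class = "revdosim_solver_error")
    }
  } else {
    mb <- rep(NA_real_, length(total))
  }

  v_ven <- unname(model$physiology$tissue_volumes["venous_blood"])
  c_ven <- amounts[, "venous_blood"] / v_ven
  pk <- refine_peak(times, c_ven)
  auc <- sum(diff(times) * (utils::head(c_ven, -1) + utils::tail(c_ven, -1)) / 2)

  structure(
    list(
      model = model,
      oral_dose = oral_dose,
      dose_umol = dose_umol,
      times = times,
      amounts = amounts,
      mass_balance = mb,
      cmax_venous_uM = pk$value,
      tmax_h = pk$time,
      cmax_unbound_uM = model$chem$fup * pk$value,
      auc_uM_h = auc
    ),
    class = "pbk_simulation"
  )
}

## quadratic refinement of a discrete maximum (local parabola through the
## three points around the grid argmax)
refine_peak <- function(t, y) {
  i <- which.max(y)
  if (i == 1 || i == length(y)) return(list(time = t[i], value = y[i]))
  ts <- t[(i - 1):(i + 1)]; ys <- y[(i - 1):(i + 1)]
  co <- stats::coef(stats::lm(ys ~ ts + I(ts^2)))
  if (!is.finite(co[3]) || co[3] >= 0) return(list(time = t[i], value = y[i]))
  tv <- -co[2] / (2 * co[3])
  if (tv < ts[1] || tv > ts[3]) return(list(time = t[i], value = y[i]))
  list(time = unname(tv), value = unname(co[1] + co[2] * tv + co[3] * tv^2))
}

#' @export
print.pbk_simulation <- function(x, ...) {
  cat(sprintf("<pbk_simulation> %s %s, %.4g mg/kg, %.3g h\n",
              x$model$chem$name, x$model$species, x$oral_dose,
              max(x$times)))
  cat(sprintf("  Cmax venous %.4g uM (unbound %.4g uM) at %.3g h; AUC %.4g uM*h\n",
              x$cmax_venous_uM, x$cmax_unbound_uM, x$tmax_h, x$auc_uM_h))
  invisible(x)
}

#' Long tidy table of a PBK simulation
#'
#' @param x A `pbk_simulation`.
#' @param ... Unused.
#' @return A tibble (`time_h`, `compartment`, `amount_umol`,
#'   `concentration_uM`); concentration is `NA` for bookkeeping states
#'   without a volume (lumen, urine, cumulative metabolised).
#' @export
tidy.pbk_simulation <- function(x, ...) {
  V <- x$model$physiology$tissue_volumes
  long <- as_tibble(as.data.frame(x$amounts)) |>
    dplyr::mutate(time_h = x$times) |>
    tidyr::pivot_longer(-"time_h", names_to = "compartment",
                        values_to = "amount_umol")
  vol <- unname(V[match(long$compartment, names(V))])
  long$concentration_uM <- long$amount_umol / vol
  long
}

#' Unbound peak blood concentration
#'
#' The dose metric of the reverse dosimetry: `fup x` the (refined) maximum
#' venous-blood concentration.
#'
#' @param result A `pbk_simulation`.
#' @param chem Optional `chemical_properties` whose `fup` overrides the
#'   model's.
#' @return Unbound Cmax, uM.
#' @export
unbound_cmax <- function(result, chem = NULL) {
  stopifnot(inherits(result, "pbk_simulation"))
  fup <- (chem %||% result$model$chem)$fup
  fup * result$cmax_venous_uM
}

#' Dose to unbound-Cmax mapping
#'
#' Simulates the model over a dose grid and returns the strictly increasing
#' dose -> unbound Cmax mapping with a monotone shape-preserving interpolator
#' (log-log monotone Hermite spline) attached. A non-monotone simulated
#' sequence signals a solver-tolerance problem and raises an error.
#'
#' @param model A [pbk_model()].
#' @param doses Dose grid, mg/kg bw, sorted and > 0. Default: 40 log-spaced
#'   doses over 1e-4 to 1e3.
#' @param hours,n_out,rtol,atol Passed to [simulate_pbk()].
#' @return A `cmax_map`: tibble (`dose_mg_kg`, `cmax_unbound_uM`) with the
#'   interpolator and model attached as attributes.
#' @export
dose_to_cmax_map <- function(model, doses = 10^seq(-4, 3, length.out = 40),
                             hours = 24, n_out = 300, rtol = 1e-8, atol = 1e-10) {
  if (any(doses <= 0) || is.unsorted(doses, strictly = TRUE)) {
    abort("doses must be > 0 and strictly increasing",
          class = "revdosim_validation_error")
  }
  cmax <- vapply(doses, function(d) {
    simulate_pbk(model, d, hours = hours, n_out = n_out,
                 rtol = rtol, atol = atol)$cmax_unbound_uM
  }, numeric(1))
  if (any(diff(cmax) <= 0)) {
    abort("simulated unbound Cmax is not strictly increasing in dose; tighten solver tolerances",
          class = "revdosim_solver_error")
  }
  out <- tibble(dose_mg_kg = doses, cmax_unbound_uM = cmax)
  attr(out, "interpolator") <- stats::splinefun(log(doses), log(cmax),
                                                method = "monoH.FC")
  attr(out, "model") <- model
  attr(out, "sim_args") <- list(hours = hours, n_out = n_out,
                                rtol = rtol, atol = atol)
  class(out) <- c("cmax_map", class(out))
  out
}

#' Cumulative urinary excretion of the glucuronidated metabolite
#'
#' Runs the rat model with the BCP sub-model enabled and returns the
#' PBK-predicted cumulative urinary excretion of BCP-glucuronide as a
#' percentage of the molar dose — the quantity compared against reported
#' in vivo excretion data for model evaluation.
#'
#' @param model A [pbk_model()] built with `bcp = TRUE`.
#' @param oral_dose mg/kg bw.
#' @param duration Simulation horizon (h), default 120.
#' @param n_out Output resolution.
#' @return A tibble (`time_h`, `cumulative_pct_dose`), non-decreasing and
#'   bounded by 100%.
#' @export
simulate_urinary_excretion <- function(model, oral_dose, duration = 120,
                                       n_out = 400) {
  stopifnot(inherits(model, "pbk_model"))
  if (is.null(model$bcp)) {
    abort("model was built without the BCP sub-model (use pbk_model(..., bcp = TRUE))",
          class = "revdosim_validation_error")
  }
  sim <- simulate_pbk(model, oral_dose, hours = duration, n_out = n_out)
  pct <- if (sim$dose_umol > 0) {
    100 * sim$amounts[, "bcp_glu_urine"] / sim$dose_umol
  } else {
    rep(0, length(sim$times))
  }
  tibble(time_h = sim$times, cumulative_pct_dose = unname(pct))
}
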