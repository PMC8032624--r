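#' Tissue composition table for partition-coefficient estimation
#'
#' Loads the packaged fractional tissue composition table (water, neutral
#' lipid, phospholipid volume fractions per tissue, plus the plasma reference
#' row) used by the tissue-composition partitioning method. The file header
#' carries the citation; the same composition values are conventionally
#' applied to rat and human.
#'
#' @param path Optional path to a user-supplied CSV with columns
#'   `tissue, water, neutral_lipid, phospholipid`.
#' @return A tibble with one row per tissue plus a `plasma` row.
#' @export
tissue_composition <- function(path = NULL) {
  path <- path %||% system.file("extdata", "tissue_composition.csv",
                                package = "revdosim", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  tab <- as_tibble(tab)
  needed <- c("tissue", "water", "neutral_lipid", "phospholipid")
  if (!all(needed %in% names(tab))) {
    abort("composition table must have columns tissue, water, neutral_lipid, phospholipid",
          class = "revdosim_validation_error")
  }
  fr <- as.matrix(tab[, c("water", "neutral_lipid", "phospholipid")])
  if (any(fr < 0 | fr > 1)) {
    abort("composition fractions must lie in [0, 1]",
          class = "revdosim_validation_error")
  }
  if (any(rowSums(fr) > 1 + 1e-9)) {
    abort("water + lipid fractions exceed 1 for at least one tissue",
          class = "revdosim_validation_error")
  }
  if (!"plasma" %in% tab$tissue) {
    abort("composition table must contain a 'plasma' row",
          class = "revdosim_validation_error")
  }
  tab
}

## Fraction of the compound in neutral form at a given pH
## (Henderson-Hasselbalch). Neutral compounds return 1.
neutral_fraction <- function(chem, pH = 7.4) {
  switch(chem$ionization,
    neutral = 1,
    acid = 1 / (1 + 10^(pH - chem$pKa)),
    base = 1 / (1 + 10^(chem$pKa - pH))
  )
}

#' Estimate tissue:plasma partition coefficients from tissue composition
#'
#' Implements the tissue-composition partitioning method (Berezhkovskiy's
#' correction of the Poulin-Theil equations) from `logKow`, `pKa` and `fup`.
#' Only the neutral species is assumed to partition into lipid
#' (Henderson-Hasselbalch speciation at pH 7.4). For non-adipose tissues the
#' octanol:water partition coefficient of the neutral form is used together
#' with the tissue-binding correction `fut = 1 / (1 + 0.5 (1 - fup) / fup)`;
#' for adipose the vegetable-oil:water coefficient
#' `logD_vo = 1.115 logKow - 1.35` is used and tissue binding is taken as
#' negligible (`fut = 1`). Blood compartments are assigned
#' `Kp = blood_plasma_ratio`. The estimator is fully deterministic.
#'
#' @param chem A [chemical_properties()] object.
#' @param table A composition table from [tissue_composition()].
#' @param pH Physiological pH for speciation (default 7.4).
#' @return A tibble (`tissue`, `kp`, `provenance = "estimated"`), one row per
#'   model compartment (blood compartments included).
#' @export
estimate_partition_coefficients <- function(chem, table = tissue_composition(),
                                            pH = 7.4) {
  stopifnot(inherits(chem, "chemical_properties"))
  fn <- neutral_fraction(chem, pH)
  P <- fn * 10^chem$logKow            # effective neutral-species Kow
  ## vegetable-oil:water coefficient for adipose; guard the degenerate P = 0
  Dvo <- if (P > 0) 10^(1.115 * log10(P) - 1.35) else 0
  fup <- chem$fup
  fut <- 1 / (1 + 0.5 * (1 - fup) / fup)

  tissues <- setdiff(PBK_COMPARTMENTS, c("venous_blood", "arterial_blood"))
  missing <- setdiff(tissues, table$tissue)
  if (length(missing) > 0) {
    abort(paste0("composition table is missing tissue(s): ",
                 paste(missing, collapse = ", ")),
          class = "revdosim_validation_error")
  }
  pl <- table[table$tissue == "plasma", ]

  kp_one <- function(t) {
    x <- table[table$tissue == t, ]
    if (t == "fat") {
      num <- Dvo * (x$neutral_lipid + 0.3 * x$phospholipid) +
        (x$water + 0.7 * x$phospholipid)
      den <- Dvo * (pl$neutral_lipid + 0.3 * pl$phospholipid) +
        (pl$water + 0.7 * pl$phospholipid)
      num / den * fup          # fut ~ 1 in adipose
    } else {
      num <- P * (x$neutral_lipid + 0.3 * x$phospholipid) +
        (x$water + 0.7 * x$phospholipid)
      den <- P * (pl$neutral_lipid + 0.3 * pl$phospholipid) +
        (pl$water + 0.7 * pl$phospholipid)
      num / den * fup / fut
    }
  }

  kp <- vapply(tissues, kp_one, numeric(1))
  out <- tibble(
    tissue = c(tissues, "venous_blood", "arterial_blood"),
    kp = c(unname(kp), chem$blood_plasma_ratio, chem$blood_plasma_ratio),
    provenance = "estimated"
  )
  out
}

#' Resolve partition coefficients, honouring user-supplied overrides
#'
#' User-supplied Kp values (from a chemical config's `partition_overrides`
#' block, or passed directly) take precedence over composition-based
#' estimation tissue by tissue; the remainder is estimated with
#' [estimate_partition_coefficients()].
#'
#' @param overrides Named numeric vector of Kp values (may be `NULL`, empty,
#'   or partial). If `chem` carries a `"partition_overrides"` attribute and
#'   `overrides` is `NULL`, the attribute is used.
#' @param chem A [chemical_properties()] object.
#' @param table Composition table.
#' @return A tibble (`tissue`, `kp`, `provenance`), with provenance
#'   `"user-supplied"` where an override applied and `"estimated"` elsewhere.
#' @export
resolve_partitions <- function(overrides = NULL, chem, table = tissue_composition()) {
  overrides <- overrides %||% attr(chem, "partition_overrides") %||% numeric(0)
  overrides <- unlist(overrides)
  est <- estimate_partition_coefficients(chem, table)
  if (length(overrides) == 0) return(est)
  unknown <- setdiff(names(overrides), est$tissue)
  if (length(unknown) > 0) {
    abort(paste0("partition override(s) for unknown tissue(s): ",
                 paste(unknown, collapse = ", ")),
          class = "revdosim_validation_error")
  }
  if (any(!is.finite(overrides) | overrides <= 0)) {
    abort("supplied Kp values must be finite and > 0",
          class = "revdosim_validation_error")
  }
  idx <- match(names(overrides), est$tissue)
  est$kp[idx] <- unname(overrides)
  est$provenance[idx] <- "user-supplied"
  est
}

## Internal: partition tibble -> named vector over all 14 compartments,
## erroring on any compartment without a Kp.
partition_vector <- function(partitions) {
  missing <- setdiff(PBK_COMPARTMENTS, partitions$tissue)
  if (length(missing) > 0) {
    abort(paste0("no partition coefficient for compartment(s): ",
                 paste(missing, collapse = ", ")),
          class = "revdosim_validation_error")
  }
  if (any(!is.finite(partitions$kp) | partitions$kp <= 0)) {
    abort("all Kp values must be finite and > 0",
          class = "revdosim_validation_error")
  }
  stats::setNames(partitions$kp[match(PBK_COMPARTMENTS, partitions$tissue)],
                  PBK_COMPARTMENTS)
}
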