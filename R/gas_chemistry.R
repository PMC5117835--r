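#' Henry-constant table for light alkanes
#'
#' Solubility constants used in headspace-equilibration calculations,
#' shipped as an editable CSV. Methane uses a temperature-dependent Bunsen
#' coefficient fit, `ln(beta) = a1 + a2*(100/T) + a3*ln(T/100)` with T in
#' kelvin (zero salinity); ethane and propane use fixed 25 degC
#' dimensionless solubilities with an optional van 't Hoff temperature
#' correction `H(T) = H25 * exp(k * (1/T - 1/298.15))`.
#'
#' @param path Optional path to an alternative constants CSV with the same
#'   columns as the shipped file.
#' @return Data frame of per-gas constants.
#' @export
henry_constants <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "henry_constants.csv",
                        package = "methanemix", mustWork = TRUE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Dimensionless Henry solubility of a gas
#'
#' Aqueous/gas-phase concentration ratio at equilibrium (C_aq / C_gas,
#' dimensionless) at the given temperature. The Bunsen coefficient beta
#' (volume of STP gas dissolved per volume of water at 1 atm partial
#' pressure) converts to the dimensionless ratio as `beta * T / 273.15`.
#'
#' @param gas One of `"methane"`, `"ethane"`, `"propane"`.
#' @param temperature_c Water temperature, degrees Celsius.
#' @param constants Constants table, see [henry_constants()].
#' @param vant_hoff Apply the van 't Hoff correction for fixed-constant
#'   gases (default TRUE).
#' @return Dimensionless solubility (aqueous over gas-phase concentration).
#' @export
#' @examples
#' henry_solubility("methane", 20)  # ~0.037
henry_solubility <- function(gas, temperature_c,
                             constants = henry_constants(),
                             vant_hoff = TRUE) {
  row <- constants[constants$gas == gas, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown gas: ", gas, call. = FALSE)
  if (temperature_c < row$temp_min_c || temperature_c > row$temp_max_c) {
    stop(sprintf("temperature %.1f degC outside validity range [%g, %g] for %s",
                 temperature_c, row$temp_min_c, row$temp_max_c, gas),
         call. = FALSE)
  }
  t_k <- temperature_c + 273.15
  if (row$model == "bunsen_fit") {
    beta <- exp(row$a1 + row$a2 * (100 / t_k) + row$a3 * log(t_k / 100))
    beta * t_k / 273.15
  } else {
    h <- row$h25_dimensionless
    if (vant_hoff) h <- h * exp(row$vant_hoff_k * (1 / t_k - 1 / 298.15))
    h
  }
}

#' Describe a headspace-equilibration setup
#'
#' Vial geometry and conditions for one analytical batch: samples are
#' injected into N2-flushed vials, shaken to equilibrium, and the gas phase
#' analysed by gas chromatography; the original dissolved concentration is
#' then recovered by mole balance.
#'
#' @param vial_volume_ml Total vial volume, ml.
#' @param water_volume_ml Water (sample) volume, ml; must be positive and
#'   at most the vial volume.
#' @param temperature_c Equilibration temperature, degC.
#' @param gas Gas species, see [henry_solubility()].
#' @param constants Henry-constant table.
#' @return List of class `"headspace_setup"`.
#' @export
headspace_setup <- function(vial_volume_ml, water_volume_ml, temperature_c,
                            gas = c("methane", "ethane", "propane"),
                            constants = henry_constants()) {
  gas <- match.arg(gas)
  if (!(water_volume_ml > 0 && water_volume_ml <= vial_volume_ml)) {
    stop("need 0 < water_volume_ml <= vial_volume_ml", call. = FALSE)
  }
  h <- henry_solubility(gas, temperature_c, constants)  # errors on bad T
  structure(list(vial_volume_ml = vial_volume_ml,
                 water_volume_ml = water_volume_ml,
                 temperature_c = temperature_c,
                 gas = gas,
                 solubility = h),
            class = "headspace_setup")
}

#' Dissolved gas concentration before headspace equilibration
#'
#' Mole balance for the headspace method: after equilibration the measured
#' gas-phase concentration `C_g` coexists with an aqueous concentration
#' `H * C_g` (H the dimensionless solubility), so the total moles in the
#' vial are `C_g * V_head + H * C_g * V_water`. Dividing by the water
#' volume recovers the original dissolved concentration. Mass is conserved
#' exactly; with no headspace the equilibrium aqueous value is returned
#' unchanged.
#'
#' @param headspace_conc Measured gas-phase concentration after
#'   equilibration, umol per litre of gas phase.
#' @param setup A [headspace_setup()].
#' @return Initial aqueous concentration, umol/l.
#' @export
#' @examples
#' s <- headspace_setup(9.83, 5.83, 20, "methane")
#' dissolved_from_headspace(10, s)
dissolved_from_headspace <- function(headspace_conc, setup) {
  stopifnot(inherits(setup, "headspace_setup"))
  stop_if_not_finite(headspace_conc, "headspace_conc")
  if (any(headspace_conc < 0)) stop("headspace_conc must be >= 0",
                                    call. = FALSE)
  v_head <- setup$vial_volume_ml - setup$water_volume_ml
  total_umol <- headspace_conc * v_head / 1000 +
    setup$solubility * headspace_conc * setup$water_volume_ml / 1000
  total_umol / (setup$water_volume_ml / 1000)
}

#' Bernard ratio C1/(C2+C3)
#'
#' Ratio of methane concentration to the summed concentrations of ethane
#' and propane. Methanogenic (microbial) methane carries essentially no
#' higher alkanes, giving very large ratios; thermogenic gas is
#' alkane-rich. The ratio is `+Inf` when no higher alkanes are present but
#' methane is, and `NaN` (undefined) when all three are zero.
#'
#' @param c1,c2,c3 Methane, ethane, propane concentrations, umol/l, >= 0.
#' @return Dimensionless ratio (possibly `Inf` or `NaN`), vectorised.
#' @export
#' @examples
#' bernard_ratio(200, 1.5, 0.5)   # 100
bernard_ratio <- function(c1, c2, c3) {
  stop_if_not_finite(c1, "c1")
  if (any(c1 < 0) || any(c2 < 0, na.rm = TRUE) || any(c3 < 0, na.rm = TRUE)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  denom <- c2 + c3
  ifelse(denom == 0 & c1 == 0, NaN,
         ifelse(denom == 0, Inf, c1 / denom))
}

#' Classify a Bernard ratio into a genetic source field
#'
#' Ratios below 100 indicate a thermogenic source, ratios above 1000 a
#' methanogenic (microbial) one; anything in between -- boundaries
#' included -- is considered a mix. Thresholds are configurable.
#'
#' @param ratio Bernard ratio(s), >= 0 or `Inf`; `NaN` yields `NA`.
#' @param thermogenic_below,methanogenic_above Classification thresholds.
#' @return Factor with levels thermogenic, mixed, methanogenic.
#' @export
#' @examples
#' classify_bernard(c(50, 100, 5000))
classify_bernard <- function(ratio, thermogenic_below = 100,
                             methanogenic_above = 1000) {
  if (any(ratio < 0, na.rm = TRUE)) stop("ratio must be >= 0", call. = FALSE)
  lab <- ifelse(is.nan(ratio), NA_character_,
         ifelse(ratio < thermogenic_below, "thermogenic",
         ifelse(ratio > methanogenic_above, "methanogenic", "mixed")))
  factor(lab, levels = c("thermogenic", "mixed", "methanogenic"))
}

#' Apply an analytical detection limit
#'
#' Concentrations below the limit are left-censored: the stored value is
#' set to the detection limit and flagged, rather than dropped or zeroed,
#' so downstream threshold filters behave deterministically.
#'
#' @param conc Concentration(s), umol/l, >= 0.
#' @param limit Detection limit, umol/l (default 0.11, the methane GC
#'   limit for the headspace method).
#' @return Data frame with columns `value` and `censored`.
#' @export
#' @examples
#' apply_detection_limit(c(0.05, 0.11, 3.2))
apply_detection_limit <- function(conc, limit = 0.11) {
  stop_if_not_finite(conc, "conc")
  if (any(conc < 0)) stop("conc must be >= 0", call. = FALSE)
  data.frame(value = pmax(conc, limit), censored = conc < limit)
}
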