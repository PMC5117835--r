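#' Radiocarbon reporting constants
#'
#' The constants of the conventional (Stuiver--Polach) radiocarbon reporting
#' system used throughout the package: the Libby mean life (8033 yr), from
#' which conventional age is `-8033 * log(F)`, and the Delta-14C floor of
#' -1000 permil, the value of radiocarbon-dead ("fossil") carbon.
#'
#' @return Named list with elements `libby_mean_life` (years) and
#'   `d14c_floor` (permil).
#' @export
#' @examples
#' rc_constants()$libby_mean_life
rc_constants <- function() {
  list(libby_mean_life = 8033, d14c_floor = -1000)
}

stop_if_not_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("`", what, "` must be finite numeric", call. = FALSE)
  }
}

#' Radiocarbon unit conversions
#'
#' Convert between the three equivalent expressions of a radiocarbon
#' measurement: conventional age (years BP, Libby mean life 8033 yr),
#' fraction modern F, and Delta-14C in permil relative to the 1950 standard.
#' Mass balance in a mixture is linear in F (equivalently Delta-14C), never
#' in age, so all mixing arithmetic in the package runs through F.
#'
#' * `fm_from_age(age)` = `exp(-age / 8033)`; negative ages (post-bomb,
#'   F > 1) are allowed and flagged downstream, never clamped.
#' * `age_from_fm(F)` = `-8033 * log(F)`; F must be > 0 -- a sample with
#'   F = 0 is radiocarbon dead and its age is unbounded.
#' * `d14c_from_fm(F)` = `(F - 1) * 1000`; F = 0 maps to -1000 permil.
#' * `fm_from_d14c(d)` = `1 + d / 1000`; requires d >= -1000.
#'
#' @param age_bp Conventional radiocarbon age, years before 1950.
#' @param fraction_modern Fraction modern, >= 0 (post-bomb samples exceed 1).
#' @param delta14c_permil Delta-14C, permil; >= -1000.
#' @return Numeric vector of the converted quantity.
#' @name radiocarbon-conversions
#' @examples
#' fm_from_age(5568)            # one Libby half-life, ~0.5
#' d14c_from_fm(fm_from_age(6900))
NULL

#' @rdname radiocarbon-conversions
#' @export
fm_from_age <- function(age_bp) {
  stop_if_not_finite(age_bp, "age_bp")
  exp(-age_bp / rc_constants()$libby_mean_life)
}

#' @rdname radiocarbon-conversions
#' @export
age_from_fm <- function(fraction_modern) {
  stop_if_not_finite(fraction_modern, "fraction_modern")
  if (any(fraction_modern <= 0)) {
    stop("fraction_modern must be > 0 (fossil carbon: age unbounded)",
         call. = FALSE)
  }
  -rc_constants()$libby_mean_life * log(fraction_modern)
}

#' @rdname radiocarbon-conversions
#' @export
d14c_from_fm <- function(fraction_modern) {
  stop_if_not_finite(fraction_modern, "fraction_modern")
  if (any(fraction_modern < 0)) {
    stop("fraction_modern must be >= 0", call. = FALSE)
  }
  (fraction_modern - 1) * 1000
}

#' @rdname radiocarbon-conversions
#' @export
fm_from_d14c <- function(delta14c_permil) {
  stop_if_not_finite(delta14c_permil, "delta14c_permil")
  if (any(delta14c_permil < rc_constants()$d14c_floor)) {
    stop("delta14c below the -1000 permil fossil floor", call. = FALSE)
  }
  1 + delta14c_permil / 1000
}

#' Construct a self-consistent radiocarbon record
#'
#' Build a data frame holding the equivalent triple (conventional age BP,
#' fraction modern, Delta-14C) from any one of the three, plus a
#' `post_bomb` flag for samples with F > 1 (Delta-14C > 0), whose
#' conventional age is negative. Radiocarbon-dead input (Delta-14C = -1000,
#' F = 0) yields `age_bp = Inf`.
#'
#' @param age_bp,fraction_modern,delta14c Exactly one must be supplied.
#' @return Data frame of class `"radiocarbon"` with columns `age_bp`,
#'   `fraction_modern`, `delta14c`, `post_bomb`.
#' @export
#' @examples
#' radiocarbon(age_bp = 6900)
#' radiocarbon(delta14c = c(-580, 25))
radiocarbon <- function(age_bp = NULL, fraction_modern = NULL,
                        delta14c = NULL) {
  given <- !c(is.null(age_bp), is.null(fraction_modern), is.null(delta14c))
  if (sum(given) != 1L) {
    stop("supply exactly one of age_bp, fraction_modern, delta14c",
         call. = FALSE)
  }
  if (!is.null(age_bp)) {
    fraction_modern <- fm_from_age(age_bp)
  } else if (!is.null(delta14c)) {
    fraction_modern <- fm_from_d14c(delta14c)
  } else {
    stop_if_not_finite(fraction_modern, "fraction_modern")
    if (any(fraction_modern < 0)) stop("fraction_modern must be >= 0",
                                       call. = FALSE)
  }
  age <- ifelse(fraction_modern > 0,
                -rc_constants()$libby_mean_life * log(fraction_modern),
                Inf)
  out <- data.frame(age_bp = age,
                    fraction_modern = fraction_modern,
                    delta14c = d14c_from_fm(fraction_modern),
                    post_bomb = fraction_modern > 1)
  class(out) <- c("radiocarbon", "data.frame")
  out
}

#' Fraction modern of a mixture
#'
#' Radiocarbon activity obeys mass balance linearly in fraction modern: a
#' mixture's F is the proportion-weighted mean of the sources' F values.
#' The conventional age of a mixed dissolved-methane sample is therefore an
#' activity-weighted average over all methane sources present, not an
#' age-weighted one.
#'
#' @param proportions Non-negative weights summing to 1 (tolerance 1e-9).
#' @param fms Fraction-modern values, same length as `proportions`.
#' @return Fraction modern of the mixture.
#' @export
#' @examples
#' mix_fraction_modern(c(0.576, 0.424), c(0, 1))  # dead + fully modern
mix_fraction_modern <- function(proportions, fms) {
  stop_if_not_finite(proportions, "proportions")
  stop_if_not_finite(fms, "fms")
  if (length(proportions) != length(fms)) {
    stop("proportions and fms must have the same length", call. = FALSE)
  }
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must be non-negative and sum to 1", call. = FALSE)
  }
  sum(proportions * fms)
}

#' Maximum radiocarbon-dead fraction of a mixture
#'
#' Upper bound on the fossil (radiocarbon-dead, F = 0) fraction of a sample
#' of given conventional age, assuming the non-fossil complement is fully
#' modern (F = 1): solving `F_mix = x * 0 + (1 - x) * 1` gives
#' `x = 1 - exp(-age / 8033)`. Any complement older than modern would only
#' lower the admissible dead fraction, so this is a maximum.
#'
#' @param age_bp_mixture Conventional age of the mixture, years BP, >= 0.
#' @return Maximum dead fraction in \[0, 1).
#' @export
#' @examples
#' max_dead_fraction(6900)  # ~0.576: the oldest aquifer methane sample
max_dead_fraction <- function(age_bp_mixture) {
  stop_if_not_finite(age_bp_mixture, "age_bp_mixture")
  if (any(age_bp_mixture < 0)) {
    stop("age_bp_mixture must be >= 0", call. = FALSE)
  }
  1 - fm_from_age(age_bp_mixture)
}
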