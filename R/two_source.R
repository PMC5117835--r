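#' Default delta-13C endmembers for the two-source model
#'
#' The organic-matter endmember is the stratified average of all measured
#' OM pools (-27.83 +/- 2.49 permil, close to the canonical -28 permil of
#' terrestrial photosynthate). The "average" MOB endmember is the mean
#' delta-13C of dissolved methane over all samples collected when methane
#' exceeded 1 umol/l (-68.79 +/- 8.52 permil, n = 32): the heaviest
#' plausible signature of methanotroph biomass. The "conservative" MOB
#' endmember (-100.86 permil) is that value shifted by the maximal
#' exponential-growth fractionation of methane-oxidizing bacteria and is
#' taken as an authoritative constant: it is the lightest plausible MOB
#' signature, and it is not exactly reproducible from -68.79 and
#' epsilon = 30.3 under either subtraction convention (see
#' [mob_endmember()]), so it is shipped as data rather than recomputed.
#'
#' @param om_d13c,om_sd Organic-matter endmember mean and sd, permil.
#' @param mob_avg,mob_avg_sd Average MOB endmember mean and sd, permil.
#' @param mob_cons Conservative MOB endmember, permil.
#' @param conc_threshold Methane concentration filter for the average
#'   endmember, umol/l (strictly greater than).
#' @return List of class `"endmember_set"`.
#' @export
default_endmembers <- function(om_d13c = -27.83, om_sd = 2.49,
                               mob_avg = -68.79, mob_avg_sd = 8.52,
                               mob_cons = -100.86,
                               conc_threshold = 1.0) {
  if (!(mob_cons < mob_avg && mob_avg < om_d13c)) {
    stop("endmembers must order mob_cons < mob_avg < om_d13c", call. = FALSE)
  }
  structure(list(om_d13c = om_d13c, om_sd = om_sd,
                 mob_avg = mob_avg, mob_avg_sd = mob_avg_sd,
                 mob_cons = mob_cons,
                 conc_threshold = conc_threshold),
            class = "endmember_set")
}

#' Two-endmember isotope mass balance
#'
#' Solve the linear mixing model `delta_mix = f * delta_a + (1-f) * delta_b`
#' for the fraction `f` of source a:
#' `f = (delta_mix - delta_b) / (delta_a - delta_b)`. The solution is the
#' exact affine inverse of the forward mixture and is deliberately not
#' clipped -- mixtures isotopically outside the endmember interval return
#' fractions outside \[0, 1\], which callers flag rather than hide.
#'
#' @param delta_mix Mixture signature, permil.
#' @param delta_source_a,delta_source_b Endmember signatures, permil; must
#'   differ.
#' @return Fraction of source a (vectorised over `delta_mix`).
#' @export
#' @examples
#' solve_two_endmember(-70.6, -100, -50)  # thermogenic bound: 1 - this
solve_two_endmember <- function(delta_mix, delta_source_a, delta_source_b) {
  stop_if_not_finite(delta_mix, "delta_mix")
  if (any(delta_source_a == delta_source_b)) {
    stop("degenerate endmembers: delta_source_a == delta_source_b",
         call. = FALSE)
  }
  (delta_mix - delta_source_b) / (delta_source_a - delta_source_b)
}

#' MOB biomass delta-13C from a methane signature
#'
#' Shift a methane delta-13C by a methanotroph fractionation factor
#' epsilon. Two conventions: `"linear"` subtracts epsilon directly;
#' `"ratio"` applies the alpha-factor form
#' `(delta + 1000) / (1 + epsilon/1000) - 1000`. Exponential-growth MOB
#' fractionation reaches 30.3 permil; normal growth about 16 permil.
#' Intended for sensitivity analyses around the shipped conservative
#' endmember.
#'
#' @param d13c_ch4 Methane delta-13C, permil.
#' @param epsilon Fractionation, permil, >= 0.
#' @param convention `"linear"` or `"ratio"`.
#' @return MOB biomass delta-13C, permil (lighter than input when
#'   epsilon > 0).
#' @export
#' @examples
#' mob_endmember(-68.79, 30.3, "linear")
#' mob_endmember(-68.79, 30.3, "ratio")
mob_endmember <- function(d13c_ch4, epsilon,
                          convention = c("linear", "ratio")) {
  convention <- match.arg(convention)
  if (any(epsilon < 0)) stop("epsilon must be >= 0", call. = FALSE)
  if (convention == "linear") {
    d13c_ch4 - epsilon
  } else {
    (d13c_ch4 + 1000) / (1 + epsilon / 1000) - 1000
  }
}

#' Average methane endmember from dissolved-methane isotope samples
#'
#' Unweighted mean and sample sd of methane delta-13C over samples
#' collected when the dissolved concentration strictly exceeded the
#' threshold (default 1 umol/l). Concentration-censored samples (below
#' detection) never qualify.
#'
#' @param samples Data frame with columns `d13c_permil`, `conc_umol_l`,
#'   and optionally `conc_censored`.
#' @param conc_threshold Strict lower concentration bound, umol/l.
#' @return List with `mean`, `sd` (NA when n = 1), `n`.
#' @export
methane_endmember_from_samples <- function(samples, conc_threshold = 1.0) {
  stopifnot(is.data.frame(samples),
            all(c("d13c_permil", "conc_umol_l") %in% names(samples)))
  keep <- !is.na(samples$conc_umol_l) & samples$conc_umol_l > conc_threshold
  if ("conc_censored" %in% names(samples)) {
    keep <- keep & !samples$conc_censored
  }
  d <- samples$d13c_permil[keep]
  d <- d[!is.na(d)]
  if (length(d) == 0L) {
    stop("no samples exceed the concentration threshold", call. = FALSE)
  }
  list(mean = mean(d),
       sd = if (length(d) > 1L) stats::sd(d) else NA_real_,
       n = length(d))
}

#' Methane-derived carbon fraction of individual biomass
#'
#' Apply the two-endmember model twice per individual: biomass delta-13C
#' against the organic-matter endmember paired with the average MOB
#' endmember (`f_avg`, the upper estimate of methane-derived carbon) and
#' with the conservative MOB endmember (`f_cons`, the lower estimate).
#' Fractions outside \[0, 1\] are returned unclipped with `out_of_range`
#' set; clipping would bias the stratified means downstream.
#'
#' @param d13c_permil Biomass delta-13C, permil VPDB (vectorised).
#' @param endmembers An `"endmember_set"`, see [default_endmembers()].
#' @return Data frame with `f_avg`, `f_cons`, `out_of_range`.
#' @export
#' @examples
#' f_methane(-55.1)  # the Nyack floodplain mean
f_methane <- function(d13c_permil, endmembers = default_endmembers()) {
  stopifnot(inherits(endmembers, "endmember_set"))
  f_avg <- solve_two_endmember(d13c_permil, endmembers$mob_avg,
                               endmembers$om_d13c)
  f_cons <- solve_two_endmember(d13c_permil, endmembers$mob_cons,
                                endmembers$om_d13c)
  data.frame(f_avg = f_avg, f_cons = f_cons,
             out_of_range = f_avg < 0 | f_avg > 1 | f_cons < 0 | f_cons > 1)
}

#' Stratified mean and standard error with wells as strata
#'
#' Per-stratum (per-well) means are computed first; the grand mean is the
#' unweighted mean of stratum means and the SE is the standard error of
#' those stratum means, treating wells as the primary sampling units.
#' With a single stratum the SE over strata is undefined and is returned
#' as NA with `n_strata = 1`.
#'
#' @param values Numeric per-individual values (fractions or delta-13C).
#' @param strata Stratum (well) identifier per value.
#' @return List with `mean`, `se`, `n_strata`, `n`, and the per-stratum
#'   means (`stratum_means`).
#' @export
#' @examples
#' stratified_summary(c(0, 0.2, 0.4, 0.6), c("a", "a", "b", "b"))
stratified_summary <- function(values, strata) {
  if (length(values) != length(strata)) {
    stop("values and strata must have the same length", call. = FALSE)
  }
  ok <- !is.na(values) & !is.na(strata)
  values <- values[ok]; strata <- strata[ok]
  if (length(values) == 0L) stop("no non-missing values", call. = FALSE)
  m <- tapply(values, strata, mean)
  k <- length(m)
  list(mean = mean(m),
       se = if (k > 1L) stats::sd(m) / sqrt(k) else NA_real_,
       n_strata = k,
       n = length(values),
       stratum_means = m)
}

#' Keeling-plot source signature
#'
#' Ordinary least squares of delta-13C on inverse concentration; in a
#' two-component (source + background) mixture the intercept at infinite
#' concentration estimates the added source's signature.
#'
#' @param concs Concentrations, umol/l, all > 0, length >= 3.
#' @param d13cs Corresponding delta-13C values, permil.
#' @return List with `intercept`, `slope`, `r2`, `n`.
#' @export
keeling_intercept <- function(concs, d13cs) {
  if (length(concs) < 3L || length(concs) != length(d13cs)) {
    stop("need >= 3 paired points", call. = FALSE)
  }
  if (any(concs <= 0)) stop("concentrations must be > 0", call. = FALSE)
  inv <- 1 / concs
  if (length(unique(inv)) < 2L) {
    stop("rank deficient: all concentrations identical", call. = FALSE)
  }
  fit <- stats::lm(d13cs ~ inv)
  s <- summary(fit)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       r2 = s$r.squared,
       n = length(concs))
}

#' Regression of biomass radiocarbon age on methane dependence
#'
#' Fits `log(age_bp + 1000)` against the per-individual average estimate of
#' methane-derived carbon. A strong positive association indicates that
#' individuals relying most on methane carry the oldest carbon, i.e. the
#' methane subsidy is ancient. Post-bomb individuals (negative conventional
#' age) enter at age 0 and are counted in `n_post_bomb`; R-squared does not
#' depend on the logarithm's base.
#'
#' @param age_bp Conventional biomass ages, years BP (negative = post-bomb).
#' @param f_avg Average methane-derived carbon fractions, same length.
#' @return List with `slope`, `intercept`, `r2`, `p_value`, `n`,
#'   `n_post_bomb`, and the `lm` fit (`fit`). With constant `f_avg` the
#'   slope is undefined: returns `slope = NA`, `r2 = 0`.
#' @export
age_dependence_regression <- function(age_bp, f_avg) {
  ok <- !is.na(age_bp) & !is.na(f_avg)
  age_bp <- age_bp[ok]; f_avg <- f_avg[ok]
  if (length(age_bp) < 3L) stop("need >= 3 complete records", call. = FALSE)
  post_bomb <- age_bp < 0
  age_bp[post_bomb] <- 0
  y <- log(age_bp + 1000)
  if (stats::var(f_avg) == 0) {
    return(list(slope = NA_real_, intercept = mean(y), r2 = 0,
                p_value = NA_real_, n = length(y),
                n_post_bomb = sum(post_bomb), fit = NULL))
  }
  fit <- stats::lm(y ~ f_avg)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = s$r.squared,
       p_value = unname(s$coefficients[2, 4]),
       n = length(y),
       n_post_bomb = sum(post_bomb),
       fit = fit)
}

#' Floodplain summary of methane-derived carbon in biomass
#'
#' Per floodplain: number of wells and individuals, stratified (well-level)
#' average and conservative percentages of methane-derived carbon, and the
#' stratified mean biomass delta-13C, each with its standard error over
#' well means. Floodplains with no usable records are dropped with a
#' warning.
#'
#' @param biomass Data frame with columns `floodplain`, `well_id`,
#'   `d13c_permil`.
#' @param endmembers An `"endmember_set"`.
#' @return Data frame, one row per floodplain, percentages on the 0--100
#'   scale.
#' @export
floodplain_table <- function(biomass, endmembers = default_endmembers()) {
  stopifnot(is.data.frame(biomass),
            all(c("floodplain", "well_id", "d13c_permil") %in% names(biomass)))
  all_fp <- unique(biomass$floodplain)
  biomass <- biomass[!is.na(biomass$d13c_permil), ]
  dropped <- setdiff(all_fp, unique(biomass$floodplain))
  if (length(dropped) > 0L) {
    warning("floodplain(s) with no usable records omitted: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (nrow(biomass) == 0L) stop("no usable biomass records", call. = FALSE)
  rows <- lapply(split(biomass, biomass$floodplain), function(b) {
    fr <- f_methane(b$d13c_permil, endmembers)
    s_avg <- stratified_summary(fr$f_avg, b$well_id)
    s_cons <- stratified_summary(fr$f_cons, b$well_id)
    s_d <- stratified_summary(b$d13c_permil, b$well_id)
    data.frame(floodplain = b$floodplain[1],
               n_wells = length(unique(b$well_id)),
               n_insects = nrow(b),
               pct_conservative = 100 * s_cons$mean,
               pct_conservative_se = 100 * s_cons$se,
               pct_average = 100 * s_avg$mean,
               pct_average_se = 100 * s_avg$se,
               mean_d13c = s_d$mean,
               mean_d13c_se = s_d$se,
               n_out_of_range = sum(fr$out_of_range))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
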