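#' Genetic-field polygons for the Schoell diagram
#'
#' Named polygons in (delta-13C, delta-2H) space delimiting methane genetic
#' fields after the standard Whiticar/Schoell diagrams: hydrogenotrophic
#' (CO2-reduction) and acetoclastic methanogenesis, a mixed methanogenic
#' field, thermogenic gas, and a combined "oxidized_or_thermogenic" field
#' for points too heavy in 13C for fresh microbial methane but outside the
#' thermogenic field proper -- residual methane left by microbial oxidation
#' is enriched in 13C and can mimic a thermogenic admixture. The published
#' diagrams draw fields, not tabulated boundaries, so the field set is
#' shipped as an editable CSV (long format: label, priority, vertex order,
#' d13c, d2h), never hard-coded.
#'
#' @param path Optional path to an alternative field CSV.
#' @return Data frame of polygon vertices with `label` and `priority`.
#' @export
genetic_fields <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "genetic_fields.csv",
                        package = "methanemix", mustWork = TRUE)
  }
  f <- utils::read.csv(path, stringsAsFactors = FALSE)
  f[order(f$priority, f$vertex), ]
}

# Ray-casting point-in-polygon with closed boundaries: a point on an edge
# or vertex counts as inside. Deterministic at the field boundaries, which
# matters because the shipped fields share edges.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  jj <- c(n, seq_len(n - 1L))
  # on-edge test: collinear and within the segment's bounding box
  for (i in seq_len(n)) {
    j <- jj[i]
    cross <- (vx[j] - vx[i]) * (py - vy[i]) - (vy[j] - vy[i]) * (px - vx[i])
    if (abs(cross) < 1e-12 &&
        px >= min(vx[i], vx[j]) - 1e-12 && px <= max(vx[i], vx[j]) + 1e-12 &&
        py >= min(vy[i], vy[j]) - 1e-12 && py <= max(vy[i], vy[j]) + 1e-12) {
      return(TRUE)
    }
  }
  inside <- FALSE
  for (i in seq_len(n)) {
    j <- jj[i]
    if ((vy[i] > py) != (vy[j] > py)) {
      xint <- vx[i] + (py - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i])
      if (px < xint) inside <- !inside
    }
  }
  inside
}

#' Classify methane samples on the Schoell diagram
#'
#' Assign each (delta-13C, delta-2H) pair the label of the first genetic
#' field, in priority order, whose polygon contains it (boundaries are
#' closed and belong to the higher-priority field); points inside no field
#' are `"unclassified"`. Samples lacking delta-2H cannot be placed on the
#' diagram -- classify those from alkane concentrations with
#' [classify_bernard()] instead.
#'
#' @param d13c_permil delta-13C of methane, permil VPDB.
#' @param d2h_permil delta-2H of methane, permil VSMOW.
#' @param fields Genetic-field polygon table, see [genetic_fields()].
#' @return Character vector of field labels.
#' @export
#' @examples
#' classify_schoell(c(-75, -40), c(-250, -150))
classify_schoell <- function(d13c_permil, d2h_permil,
                             fields = genetic_fields()) {
  if (length(d13c_permil) != length(d2h_permil)) {
    stop("d13c_permil and d2h_permil must have the same length", call. = FALSE)
  }
  if (any(is.na(d2h_permil))) {
    stop("missing delta-2H: use classify_bernard() on alkane concentrations",
         call. = FALSE)
  }
  if (nrow(fields) > 0 && anyDuplicated(unique(fields[c("label", "priority")])$label)) {
    stop("field labels must be unique", call. = FALSE)
  }
  labels <- unique(fields$label[order(fields$priority)])
  vapply(seq_along(d13c_permil), function(i) {
    for (lab in labels) {
      poly <- fields[fields$label == lab, ]
      if (point_in_polygon(d13c_permil[i], d2h_permil[i],
                           poly$d13c, poly$d2h)) {
        return(lab)
      }
    }
    "unclassified"
  }, character(1))
}

#' Residual methane delta-13C after partial microbial oxidation
#'
#' Rayleigh distillation of the residual methane pool: methane-oxidizing
#' bacteria preferentially consume 12C-methane, so the residual pool grows
#' heavier as the oxidized fraction increases. In the small-delta linear
#' approximation, `delta_residual = delta_initial - epsilon * ln(1 - f)`,
#' which is additive in the initial value; the exact ratio form
#' `(delta + 1000) * (1 - f)^(-eps/1000) - 1000` is available behind
#' `exact = TRUE`.
#'
#' @param d13c_initial Initial delta-13C of the methane pool, permil.
#' @param fraction_oxidized Fraction of the pool consumed, in \[0, 1).
#' @param epsilon_ox Kinetic fractionation of oxidation, permil (positive:
#'   residual gets heavier).
#' @param exact Use the exact Rayleigh ratio form.
#' @return Residual delta-13C, permil.
#' @export
#' @examples
#' rayleigh_residual(-70, 1 - exp(-1), 25)  # -45: one e-folding
rayleigh_residual <- function(d13c_initial, fraction_oxidized, epsilon_ox,
                              exact = FALSE) {
  stop_if_not_finite(fraction_oxidized, "fraction_oxidized")
  if (any(fraction_oxidized < 0 | fraction_oxidized >= 1)) {
    stop("fraction_oxidized must be in [0, 1)", call. = FALSE)
  }
  if (exact) {
    (d13c_initial + 1000) * (1 - fraction_oxidized)^(-epsilon_ox / 1000) - 1000
  } else {
    d13c_initial + epsilon_ox * (-log(1 - fraction_oxidized))
  }
}
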