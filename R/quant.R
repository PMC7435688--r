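#' Fit a linear standard curve
#'
#' Least-squares line response = slope x concentration + intercept for a
#' dilution series of reference standards.
#'
#' @param known_concentrations at least two distinct concentrations.
#' @param responses instrument responses, same length.
#' @param analyte optional analyte name.
#' @return List of class `standard_curve`: slope, intercept, r_squared,
#'   analyte.
#' @export
fit_standard_curve <- function(known_concentrations, responses, analyte = "") {
  if (length(known_concentrations) != length(responses)) {
    stop("concentrations and responses must have equal length", call. = FALSE)
  }
  if (length(unique(known_concentrations)) < 2) {
    stop("need at least two distinct concentrations", call. = FALSE)
  }
  fit <- lm(responses ~ known_concentrations)
  r2 <- if (sd(responses) == 0) 1 else
    .quiet_perfect_fit(summary(fit)$r.squared)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2, analyte = analyte),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard curve%s: response = %.4g x conc + %.4g (r^2 = %.4f)\n",
              if (nzchar(x$analyte)) paste0(" [", x$analyte, "]") else "",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Inverse-predict concentrations from a standard curve
#'
#' conc = (response - intercept) / slope, times an optional dilution
#' factor.  Negative predictions (responses below the curve) are returned
#' but flagged via the `"below_curve"` attribute.
#'
#' @param responses instrument responses.
#' @param curve a [fit_standard_curve()] result with non-zero slope.
#' @param dilution multiplicative dilution factor applied after inversion.
#' @return Concentrations in the units of the calibration standards.
#' @export
quantify <- function(responses, curve, dilution = 1) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) stop("standard curve has zero slope; not invertible",
                             call. = FALSE)
  conc <- (responses - curve$intercept) / curve$slope * dilution
  if (any(conc < 0)) attr(conc, "below_curve") <- which(conc < 0)
  conc
}

#' Sterol molar ratios within a sample
#'
#' Each concentration divided by the summed concentrations of the measured
#' sterols (cholesterol, cholestenone, coprostanol) in the same sample.
#'
#' @param concentrations non-negative concentrations (same molar units);
#'   names are preserved.
#' @return Fractions summing to 1.
#' @export
molar_ratios <- function(concentrations) {
  if (any(concentrations < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  total <- sum(concentrations)
  if (total == 0) stop("all concentrations are zero; molar ratios undefined",
                       call. = FALSE)
  concentrations / total
}
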