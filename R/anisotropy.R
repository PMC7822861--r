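#' Polarized fluorescence intensities
#'
#' The four intensities measured with vertical (V) or horizontal (H)
#' polarizer/analyser positions, in arbitrary units. \code{I_VV} and
#' \code{I_VH} enter the anisotropy formula; \code{I_HV} and \code{I_HH}
#' yield the grating factor correcting for polarization-dependent detection.
#'
#' @param I_VV,I_VH,I_HV,I_HH non-negative intensities.
#' @return An object of class \code{"polarized_intensities"}.
#' @export
polarized_intensities <- function(I_VV, I_VH, I_HV = NA_real_,
                                  I_HH = NA_real_) {
  x <- c(I_VV = I_VV, I_VH = I_VH, I_HV = I_HV, I_HH = I_HH)
  if (any(x < 0, na.rm = TRUE)) stop("intensities must be non-negative")
  structure(x, class = "polarized_intensities")
}

#' Grating factor
#'
#' Instrument correction \code{G = I_HV / I_HH} compensating the
#' polarization-dependent transmission of the detection path.
#'
#' @param I a \code{"polarized_intensities"} with \code{I_HV} and
#'   \code{I_HH} present; \code{I_HH} must be positive.
#' @return Dimensionless scalar \code{G}.
#' @export
grating_factor <- function(I) {
  stopifnot(inherits(I, "polarized_intensities"))
  if (is.na(I[["I_HV"]]) || is.na(I[["I_HH"]])) {
    stop("grating factor needs I_HV and I_HH")
  }
  if (I[["I_HH"]] <= 0) {
    stop("invalid calibration measurement: I_HH must be > 0")
  }
  unname(I[["I_HV"]] / I[["I_HH"]])
}

#' Anisotropy from polarized intensities
#'
#' Standard steady-state anisotropy
#' \deqn{r = (I_{VV} - G I_{VH}) / (I_{VV} + 2 G I_{VH}),}
#' which lies in (-0.5, 1] for non-negative intensities.
#'
#' @param I a \code{"polarized_intensities"} (only \code{I_VV}, \code{I_VH}
#'   are used).
#' @param G grating factor, e.g. from [grating_factor()].
#' @return Anisotropy \code{r}.
#' @export
anisotropy_from_intensities <- function(I, G) {
  stopifnot(inherits(I, "polarized_intensities"))
  den <- I[["I_VV"]] + 2 * G * I[["I_VH"]]
  if (den <= 0) stop("invalid measurement: I_VV + 2*G*I_VH must be > 0")
  unname((I[["I_VV"]] - G * I[["I_VH"]]) / den)
}

#' Anisotropy calibration (r_min / r_max)
#'
#' The two extreme anisotropy values of the labelled nucleotide:
#' \code{r_min}, measured with only free label in solution, and
#' \code{r_max}, measured with the label fully protein-bound (determined
#' either by pelleting label bound to F-actin, or by stripping free label
#' with ion-exchange resin; the provenance tag records which). All
#' intermediate anisotropies are interpreted on the linear scale between the
#' two, which assumes the label's total fluorescence intensity is
#' independent of occupancy.
#'
#' @param r_min anisotropy of the fully free labelled species.
#' @param r_max anisotropy of the fully bound labelled species;
#'   \code{0 <= r_min < r_max <= 0.4} (one-photon limit).
#' @param method provenance of r_max: \code{"F-actin-pelleting"},
#'   \code{"Dowex"} or \code{"synthetic"}.
#' @return An object of class \code{"anisotropy_calibration"}.
#' @export
anisotropy_calibration <- function(r_min, r_max,
                                   method = c("F-actin-pelleting", "Dowex",
                                              "synthetic")) {
  method <- match.arg(method)
  if (!is.numeric(r_min) || !is.numeric(r_max) ||
      length(r_min) != 1L || length(r_max) != 1L) {
    stop("r_min and r_max must be single numbers")
  }
  if (r_min < 0 || r_max > 0.4 || r_min >= r_max) {
    stop("need 0 <= r_min < r_max <= 0.4")
  }
  structure(list(r_min = r_min, r_max = r_max, method = method,
                 assumption = "occupancy-independent total fluorescence"),
            class = "anisotropy_calibration")
}

#' @export
print.anisotropy_calibration <- function(x, ...) {
  cat(sprintf("Anisotropy calibration: r_min = %g, r_max = %g (%s)\n",
              x$r_min, x$r_max, x$method))
  invisible(x)
}

#' Shipped calibration for ATP-Cy5
#'
#' The published calibration pair for the Cy5-labelled analogue:
#' r_min = 0.242, r_max = 0.295 (F-actin pelleting method).
#' @return An \code{"anisotropy_calibration"}.
#' @export
cy5_calibration <- function() {
  anisotropy_calibration(0.242, 0.295, method = "F-actin-pelleting")
}

#' Bound fraction (occupancy) from anisotropy
#'
#' Linear binding scale between the calibration extremes:
#' \code{fraction = (r - r_min) / (r_max - r_min)}. Readings pushed outside
#' the calibrated range by noise are clipped to [0, 1] with a warning
#' reporting how many samples were affected, so downstream mass balances
#' stay physical while calibration drift is surfaced.
#'
#' @param r anisotropy value(s).
#' @param cal an \code{"anisotropy_calibration"}.
#' @return Bound fraction(s) in [0, 1].
#' @examples
#' # steady-state reading r = 0.268 on the ATP-Cy5 calibration: 49% occupancy
#' bound_fraction(0.268, cy5_calibration())
#' @export
bound_fraction <- function(r, cal) {
  stopifnot(inherits(cal, "anisotropy_calibration"))
  span <- cal$r_max - cal$r_min
  if (span <= 0) stop("degenerate calibration: r_max must exceed r_min")
  f <- (r - cal$r_min) / span
  n_out <- sum(f < 0 | f > 1)
  if (n_out > 0) {
    warning(sprintf("%d anisotropy value(s) outside [r_min, r_max]; clipped",
                    n_out))
    f <- pmin(pmax(f, 0), 1)
  }
  f
}

#' Anisotropy from bound fraction
#'
#' Exact inverse of [bound_fraction()] on [0, 1]:
#' \code{r = r_min + fraction * (r_max - r_min)}.
#'
#' @param fraction bound fraction(s), each in [0, 1].
#' @param cal an \code{"anisotropy_calibration"}.
#' @return Anisotropy value(s).
#' @export
r_from_bound_fraction <- function(fraction, cal) {
  stopifnot(inherits(cal, "anisotropy_calibration"))
  if (any(fraction < 0 | fraction > 1)) {
    stop("fraction must lie in [0, 1]")
  }
  cal$r_min + fraction * (cal$r_max - cal$r_min)
}

#' Convert an anisotropy time course to bound/free concentrations
#'
#' Applies the linear calibration sample-by-sample: bound label
#' \code{= bound_fraction(r) * S_total}, free \code{= S_total - bound}.
#' Carries the constant-total-fluorescence assumption into the output
#' metadata.
#'
#' @param tc a \code{"timecourse"} of kind \code{"anisotropy"}.
#' @param cal an \code{"anisotropy_calibration"}.
#' @param S_total total labelled analogue (uM); defaults to the value in the
#'   attached experiment if present.
#' @return A \code{"timecourse"} of kind \code{"bound_concentration"}.
#' @export
concentrations_from_timecourse <- function(tc, cal, S_total = NULL) {
  stopifnot(inherits(tc, "timecourse"))
  if (timecourse_kind(tc) != "anisotropy") {
    stop("tc must be an anisotropy time course")
  }
  ex <- attr(tc, "experiment")
  if (is.null(S_total)) {
    if (is.null(ex)) stop("S_total not given and no experiment attached")
    S_total <- ex$S_total
  }
  if (S_total <= 0) stop("S_total must be > 0")
  bound <- bound_fraction(tc$r, cal) * S_total
  meta <- attr(tc, "meta")
  meta$calibration <- cal
  meta$assumption <- cal$assumption
  new_timecourse(data.frame(time = tc$time, bound = bound,
                            free = S_total - bound),
                 kind = "bound_concentration", experiment = ex, meta = meta)
}
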