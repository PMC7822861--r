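#' Default synthetic calibration for the ATTO-488-labelled analogue
#'
#' A plausible r_min/r_max pair for a ~4 ns fluorescence-lifetime dye free
#' in solution versus bound to G-actin: r_min = 0.05, r_max = 0.22. Marked
#' with the \code{"synthetic"} provenance tag; the published calibration
#' numbers in this package are those of the Cy5 analogue
#' ([cy5_calibration()]).
#'
#' @return An \code{"anisotropy_calibration"}.
#' @export
atto488_synthetic_calibration <- function() {
  anisotropy_calibration(0.05, 0.22, method = "synthetic")
}

# additive Gaussian noise on anisotropy; sd = 0 leaves the trace untouched
.add_r_noise <- function(r, sd, seed = NULL) {
  if (sd < 0) stop("noise sd must be >= 0")
  if (sd == 0) return(r)
  if (is.null(seed)) stop("a seed is required whenever noise sd > 0")
  set.seed(as.integer(seed))
  r + stats::rnorm(length(r), sd = sd)
}

# simulate one condition and map it into anisotropy space through cal
.synth_trace <- function(experiment, rates, cal, noise_sd, seed) {
  sim <- simulate_exchange(experiment, rates)
  frac <- if (experiment$S_total > 0) sim$AS / experiment$S_total else
    rep(0, nrow(sim))
  r <- r_from_bound_fraction(frac, cal)
  r <- .add_r_noise(r, noise_sd, seed)
  new_timecourse(data.frame(time = sim$time, r = r),
                 kind = "anisotropy", experiment = experiment,
                 meta = list(calibration = cal, noise_sd = noise_sd,
                             seed = seed,
                             rates = unclass(rates),
                             assumption = cal$assumption))
}

#' Synthetic association bundle
#'
#' Generates one anisotropy time course per labelled-analogue concentration
#' for the standard association assay: fully ATP-loaded G-actin (free ATP at
#' a two-fold excess over actin) mixed with the labelled analogue, sampled
#' every \code{dt} seconds. Defaults reproduce the reference design: 2 uM
#' actin, analogue at 25-200 nM, 10-s sampling over 1800 s. Each trace is
#' the exact mass-action solution mapped to anisotropy through \code{cal},
#' plus additive Gaussian noise of standard deviation \code{noise_sd} on r.
#' Metadata on every trace records the totals, calibration, scenario and
#' seed needed to refit it.
#'
#' @param rates a \code{"rate_constants"}; default the published
#'   ATP-ATTO-488 set.
#' @param A_total total G-actin, uM.
#' @param S_totals vector of total labelled-analogue concentrations, uM.
#' @param noise_sd Gaussian noise sd on anisotropy; default 0.002
#'   (configurable; of the order of twice the reported +/-0.001 precision of
#'   plateau anisotropy means).
#' @param seed integer seed; required when \code{noise_sd > 0}. Each trace
#'   uses a distinct sub-seed derived from it.
#' @param cal an \code{"anisotropy_calibration"}; default the synthetic
#'   ATTO-488 pair.
#' @param scenario scenario modifiers or preset name; default baseline.
#' @param duration,dt observation window and sampling interval (s).
#' @return A list of \code{"timecourse"} objects of kind
#'   \code{"anisotropy"}, named by analogue concentration.
#' @export
synth_association_bundle <- function(rates = atto488_rates(), A_total = 2,
                                     S_totals = c(0.025, 0.05, 0.1, 0.2),
                                     noise_sd = 0.002, seed = NULL,
                                     cal = atto488_synthetic_calibration(),
                                     scenario = scenario_preset("Mg_baseline"),
                                     duration = 1800, dt = 10) {
  if (noise_sd > 0 && is.null(seed)) {
    stop("a seed is required whenever noise_sd > 0")
  }
  traces <- lapply(seq_along(S_totals), function(i) {
    ex <- exchange_experiment(A_total = A_total, S_total = S_totals[i],
                              duration = duration, dt = dt,
                              scenario = scenario)
    sub_seed <- if (is.null(seed)) NULL else as.integer(seed) + i - 1L
    .synth_trace(ex, rates, cal, noise_sd, sub_seed)
  })
  names(traces) <- sprintf("S%g_uM", S_totals)
  traces
}

#' Synthetic ATP-chase time course
#'
#' Association is simulated first (default 1800 s, reaching the exchange
#' steady state), then a large excess of unlabelled ATP (default 100 uM) is
#' added as an instantaneous step of free ATP; rebinding of the labelled
#' analogue is suppressed and its dissociation dominates the decay back
#' towards r_min.
#'
#' @inheritParams synth_association_bundle
#' @param S_total total labelled analogue, uM (default 0.2, the highest
#'   association concentration).
#' @param chase_T_add ATP added at the chase, uM.
#' @param chase_time time of the chase addition (s).
#' @param duration total observation time (s), beyond \code{chase_time}.
#' @return A \code{"timecourse"} of kind \code{"anisotropy"}.
#' @export
synth_chase <- function(rates = atto488_rates(), A_total = 2, S_total = 0.2,
                        chase_T_add = 100, chase_time = 1800,
                        noise_sd = 0.002, seed = NULL,
                        cal = atto488_synthetic_calibration(),
                        scenario = scenario_preset("Mg_baseline"),
                        duration = 7200, dt = 10) {
  if (noise_sd > 0 && is.null(seed)) {
    stop("a seed is required whenever noise_sd > 0")
  }
  ex <- exchange_experiment(A_total = A_total, S_total = S_total,
                            duration = duration, dt = dt,
                            chase = list(time = chase_time,
                                         T_add = chase_T_add),
                            scenario = scenario)
  .synth_trace(ex, rates, cal, noise_sd,
               if (is.null(seed)) NULL else as.integer(seed))
}

#' Synthetic equilibrium titration
#'
#' Anisotropy of a fixed concentration of labelled ABP titrated with
#' G-actin, generated from the quadratic binding isotherm
#' ([titration_model_eval()]) plus additive Gaussian noise. The two
#' reference designs are 0.5 uM labelled profilin and 2 uM labelled
#' ADF/cofilin against 0-20 uM G-actin.
#'
#' @param params a \code{"titration_params"} (generating values).
#' @param ABP_total total labelled ABP, uM.
#' @param G_grid total G-actin concentrations, uM; default 12 points on
#'   [0, 20].
#' @param noise_sd Gaussian noise sd on r; default 0.002.
#' @param seed integer seed; required when \code{noise_sd > 0}.
#' @return A \code{"titration"} dataset with generating parameters in its
#'   metadata.
#' @export
synth_titration <- function(params, ABP_total,
                            G_grid = seq(0, 20, length.out = 12),
                            noise_sd = 0, seed = NULL) {
  stopifnot(inherits(params, "titration_params"))
  r <- titration_model_eval(params, G_grid, ABP_total)
  if (noise_sd > 0 && is.null(seed)) {
    stop("a seed is required whenever noise_sd > 0")
  }
  r <- .add_r_noise(r, noise_sd, seed)
  titration_dataset(G_grid, r, ABP_total,
                    meta = list(generating = unclass(params),
                                noise_sd = noise_sd, seed = seed))
}

#' Synthetic polarized intensities realizing a target anisotropy
#'
#' Inverts the anisotropy formula: for a target \code{r} and total
#' (polarization-summed) intensity \code{I_VV + 2 G I_VH}, returns one
#' valid set of polarized intensities such that
#' [anisotropy_from_intensities()] recovers \code{r} exactly. Used to test
#' the observation layer.
#'
#' @param r_target target anisotropy in (-0.5, 1].
#' @param total_intensity the denominator \code{I_VV + 2 G I_VH}, > 0.
#' @param G grating factor, > 0.
#' @return A \code{"polarized_intensities"} with \code{I_HV = I_HH = 1}
#'   (consistent with the supplied G when G = 1, otherwise scaled so that
#'   \code{I_HV / I_HH = G}).
#' @export
synth_polarized_intensities <- function(r_target, total_intensity = 4,
                                        G = 1) {
  if (r_target <= -0.5 || r_target > 1) {
    stop("r_target must lie in (-0.5, 1]")
  }
  if (total_intensity <= 0 || G <= 0) {
    stop("total_intensity and G must be > 0")
  }
  I_VV <- total_intensity * (1 + 2 * r_target) / 3
  I_VH <- total_intensity * (1 - r_target) / (3 * G)
  polarized_intensities(I_VV = I_VV, I_VH = I_VH, I_HV = G, I_HH = 1)
}
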