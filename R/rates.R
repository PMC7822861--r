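#' Rate constants of competitive nucleotide exchange
#'
#' Bundle the four mass-action rate constants of the two-ligand exchange
#' scheme on G-actin: unlabelled ATP (subscript \code{T}) and a fluorescent
#' ATP analogue (subscript \code{S}, for the labelled species) compete for the
#' single nucleotide-binding cleft,
#' \deqn{A + T \rightleftharpoons AT, \qquad A + S \rightleftharpoons AS.}
#'
#' Units are fixed package-wide: concentrations in micromolar, time in
#' seconds, so association constants are in 1/(uM s) and dissociation
#' constants in 1/s.
#'
#' @param k_on_T association rate constant of unlabelled ATP (1/(uM s)).
#' @param k_on_S association rate constant of the labelled analogue (1/(uM s)).
#' @param k_off_T dissociation rate constant of unlabelled ATP (1/s).
#' @param k_off_S dissociation rate constant of the labelled analogue (1/s).
#' @return An object of class \code{"rate_constants"}: a named numeric vector
#'   with the four constants and attributes \code{Kd_T} and \code{Kd_S}
#'   (equilibrium dissociation constants, uM).
#' @seealso [atto488_rates()] for the published ATP-ATTO-488 parameter set,
#'   [apply_scenario()] for buffer/cation/ABP modifications.
#' @examples
#' rt <- rate_constants(10, 12, 2.8e-3, 1e-3)
#' kd(rt)
#' @export
rate_constants <- function(k_on_T, k_on_S, k_off_T, k_off_S) {
  k <- c(k_on_T = k_on_T, k_on_S = k_on_S,
         k_off_T = k_off_T, k_off_S = k_off_S)
  if (length(k) != 4L || !is.numeric(k)) {
    stop("all four rate constants must be single numeric values")
  }
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("rate constants must be strictly positive and finite")
  }
  structure(k, class = "rate_constants")
}

#' Published rate constants for ATP-ATTO-488 exchange on Mg-G-actin
#'
#' The reference parameter set for exchange of ATP and the N6-hexyl-linked
#' ATTO-488 ATP analogue on magnesium-bound G-actin:
#' k_on,ATP = 10 /(uM s), k_on,analogue = 12 /(uM s),
#' k_off,ATP = 2.8e-3 /s, k_off,analogue = 1e-3 /s.
#' Only the ratio of the two association constants is identifiable from
#' exchange kinetics (see [identifiability_profile()]); the individual
#' k_on values are conventional anchors.
#'
#' @return A \code{"rate_constants"} object.
#' @export
atto488_rates <- function() {
  rate_constants(k_on_T = 10, k_on_S = 12, k_off_T = 2.8e-3, k_off_S = 1e-3)
}

#' Equilibrium dissociation constants
#'
#' @param rates a \code{"rate_constants"} object.
#' @return Named numeric vector \code{c(Kd_T, Kd_S)} in uM
#'   (\code{Kd = k_off / k_on}).
#' @export
kd <- function(rates) {
  stopifnot(inherits(rates, "rate_constants"))
  c(Kd_T = unname(rates["k_off_T"] / rates["k_on_T"]),
    Kd_S = unname(rates["k_off_S"] / rates["k_on_S"]))
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Nucleotide-exchange rate constants (uM, s units)\n")
  cat(sprintf("  k_on,ATP    = %g /(uM s)    k_off,ATP    = %g /s\n",
              x["k_on_T"], x["k_off_T"]))
  cat(sprintf("  k_on,label  = %g /(uM s)    k_off,label  = %g /s\n",
              x["k_on_S"], x["k_off_S"]))
  kds <- kd(x)
  cat(sprintf("  Kd,ATP = %.3g uM   Kd,label = %.3g uM\n",
              kds["Kd_T"], kds["Kd_S"]))
  invisible(x)
}

#' Scenario modifiers: net fold-change of exchange speed
#'
#' Buffer composition (bound divalent cation, KCl) and nucleotide-exchange
#' ABPs (profilin, ADF/cofilin) change the observed speed of nucleotide
#' exchange by a net fold factor. Exchange from fully ATP-loaded actin is
#' dissociation-limited, so the package applies the multiplier to both
#' dissociation rate constants and leaves the association constants
#' untouched; which microscopic constants actually move is not resolved by
#' net fold-changes alone.
#'
#' @param exchange_multiplier positive scalar; 1 is the Mg2+, no-KCl baseline.
#' @param label free-text condition label stored with the modifier.
#' @return An object of class \code{"scenario_modifiers"}.
#' @seealso [scenario_preset()] for the shipped named conditions.
#' @export
scenario_modifiers <- function(exchange_multiplier = 1, label = "custom") {
  if (!is.numeric(exchange_multiplier) || length(exchange_multiplier) != 1L ||
      !is.finite(exchange_multiplier) || exchange_multiplier <= 0) {
    stop("exchange_multiplier must be a single positive finite number")
  }
  structure(list(exchange_multiplier = exchange_multiplier,
                 label = as.character(label)[1L]),
            class = "scenario_modifiers")
}

#' @export
print.scenario_modifiers <- function(x, ...) {
  cat(sprintf("Scenario '%s': exchange x%g\n", x$label, x$exchange_multiplier))
  invisible(x)
}

# shipped condition presets; multipliers are the net fold-changes of exchange
# speed reported for each condition relative to the Mg2+ no-KCl baseline
.scenario_presets <- list(
  Mg_baseline         = c(mult = 1.0),
  Ca                  = c(mult = 0.2),   # Ca2+-actin exchanges 5x slower
  Mg_KCl              = c(mult = 2.0),   # +50 mM KCl, 2x faster
  profilin_saturating = c(mult = 3.5),   # profilin accelerates 3-4x
  cofilin_inhibited   = c(mult = 0.3)    # ADF/cofilin inhibits exchange
)

#' Named scenario presets
#'
#' Shipped conditions: \code{Mg_baseline} (1.0), \code{Ca} (0.2; Ca2+-bound
#' actin exchanges five-fold slower than Mg2+-bound), \code{Mg_KCl} (2.0;
#' 50 mM KCl doubles the exchange rate), \code{profilin_saturating} (3.5;
#' profilin catalyses exchange three- to four-fold), \code{cofilin_inhibited}
#' (0.3; ADF/cofilin inhibits exchange).
#'
#' @param name one of the preset names; see Details.
#' @return A \code{"scenario_modifiers"} object.
#' @export
scenario_preset <- function(name = c("Mg_baseline", "Ca", "Mg_KCl",
                                     "profilin_saturating",
                                     "cofilin_inhibited")) {
  name <- match.arg(name)
  scenario_modifiers(.scenario_presets[[name]][["mult"]], label = name)
}

#' Apply a scenario modifier to a rate-constant set
#'
#' Multiplies both dissociation rate constants by the scenario's
#' \code{exchange_multiplier}; association constants are unchanged.
#'
#' @param rates a \code{"rate_constants"} object.
#' @param mod a \code{"scenario_modifiers"} object, or a preset name accepted
#'   by [scenario_preset()].
#' @return A new \code{"rate_constants"} object.
#' @examples
#' apply_scenario(atto488_rates(), scenario_preset("Ca"))
#' @export
apply_scenario <- function(rates, mod) {
  stopifnot(inherits(rates, "rate_constants"))
  if (is.character(mod)) mod <- scenario_preset(mod)
  if (!inherits(mod, "scenario_modifiers")) {
    stop("'mod' must be a scenario_modifiers object or a preset name")
  }
  rate_constants(k_on_T  = unname(rates["k_on_T"]),
                 k_on_S  = unname(rates["k_on_S"]),
                 k_off_T = unname(rates["k_off_T"]) * mod$exchange_multiplier,
                 k_off_S = unname(rates["k_off_S"]) * mod$exchange_multiplier)
}
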