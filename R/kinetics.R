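#' Mixture state of the exchange reaction
#'
#' Concentrations (uM) of the five chemical species of the competitive
#' exchange scheme: free nucleotide-free G-actin (\code{A}), the
#' G-actin.ATP complex (\code{AT}), the G-actin.analogue complex
#' (\code{AS}), free ATP (\code{T}) and free labelled analogue (\code{S}).
#'
#' @param A,AT,AS,T,S species concentrations in uM, all non-negative.
#' @return A named numeric vector of class \code{"mixture_state"}.
#' @export
mixture_state <- function(A = 0, AT = 0, AS = 0, T = 0, S = 0) {
  x <- c(A = A, AT = AT, AS = AS, T = T, S = S)
  if (any(!is.finite(x))) stop("concentrations must be finite")
  if (any(x < 0)) stop("concentrations must be non-negative")
  structure(x, class = "mixture_state")
}

#' @export
print.mixture_state <- function(x, ...) {
  cat("Mixture state (uM):\n")
  print(unclass(round(x, 6)))
  invisible(x)
}

#' Mass-action time derivatives of the exchange scheme
#'
#' Right-hand side of the deterministic rate equations for
#' \eqn{A + T \rightleftharpoons AT} and \eqn{A + S \rightleftharpoons AS}:
#' \deqn{dAT/dt = k_{on,T} A T - k_{off,T} AT}
#' \deqn{dAS/dt = k_{on,S} A S - k_{off,S} AS}
#' with \eqn{dA/dt = -(dAT/dt + dAS/dt)}, \eqn{dT/dt = -dAT/dt} and
#' \eqn{dS/dt = -dAS/dt}, so total actin, total ATP and total analogue are
#' conserved exactly.
#'
#' @param state a \code{"mixture_state"} (or named numeric with the same
#'   five components), uM.
#' @param rates a \code{"rate_constants"} object.
#' @return Named numeric vector of derivatives (uM/s) for
#'   \code{A, AT, AS, T, S}.
#' @export
mass_action_rhs <- function(state, rates) {
  stopifnot(inherits(rates, "rate_constants"))
  x <- unclass(state)
  need <- c("A", "AT", "AS", "T", "S")
  if (!all(need %in% names(x))) stop("state must contain A, AT, AS, T, S")
  x <- x[need]
  if (any(x < 0)) stop("concentrations must be non-negative")
  dAT <- rates[["k_on_T"]] * x[["A"]] * x[["T"]] - rates[["k_off_T"]] * x[["AT"]]
  dAS <- rates[["k_on_S"]] * x[["A"]] * x[["S"]] - rates[["k_off_S"]] * x[["AS"]]
  c(A = -(dAT + dAS), AT = dAT, AS = dAS, T = -dAT, S = -dAS)
}

#' Define a nucleotide-exchange experiment
#'
#' Describes one cuvette: total concentrations, initial loading, an optional
#' ATP chase, a condition scenario, and the sampling grid.
#'
#' The default \code{"fully_loaded"} convention reflects how monomeric actin
#' is prepared: purified G-actin carries one ATP per monomer, and dilution
#' into nucleotide-free buffer sets the remaining free ATP. With a two-fold
#' excess of free ATP over actin the totals satisfy
#' \code{T_total = 3 * A_total} (one bound equivalent plus two free), which is
#' the package default. Initial state under this convention:
#' \code{AT(0) = A_total}, \code{A(0) = AS(0) = 0},
#' \code{T(0) = T_total - A_total}, \code{S(0) = S_total}.
#'
#' @param A_total total G-actin (uM).
#' @param S_total total labelled analogue (uM).
#' @param T_total total ATP (uM, bound + free); default \code{3 * A_total}.
#' @param duration total observation time (s).
#' @param dt sampling interval (s), default 10 s.
#' @param chase optional list \code{list(time = , T_add = )}: at \code{time}
#'   seconds (strictly inside \code{(0, duration)}) \code{T_add} uM of free
#'   ATP is added instantaneously.
#' @param scenario a \code{"scenario_modifiers"} object or preset name;
#'   default the Mg2+ baseline.
#' @param init optional custom initial \code{"mixture_state"}; overrides the
#'   fully-loaded convention. Its totals must equal \code{A_total},
#'   \code{T_total}, \code{S_total}.
#' @return An object of class \code{"exchange_experiment"}.
#' @export
exchange_experiment <- function(A_total, S_total, T_total = 3 * A_total,
                                duration = 1800, dt = 10,
                                chase = NULL,
                                scenario = scenario_preset("Mg_baseline"),
                                init = NULL) {
  if (is.character(scenario)) scenario <- scenario_preset(scenario)
  stopifnot(inherits(scenario, "scenario_modifiers"))
  if (any(c(A_total, S_total, T_total) < 0)) stop("totals must be >= 0")
  if (duration <= 0) stop("duration must be > 0")
  if (dt <= 0) stop("sampling interval dt must be > 0")
  if (!is.null(chase)) {
    if (!is.list(chase) || !all(c("time", "T_add") %in% names(chase))) {
      stop("chase must be list(time = , T_add = )")
    }
    if (chase$time <= 0 || chase$time >= duration) {
      stop("chase time must lie strictly inside (0, duration)")
    }
    if (chase$T_add < 0) stop("chase T_add must be >= 0")
  }
  if (is.null(init)) {
    if (T_total < A_total) {
      stop("fully-ATP-loaded convention needs T_total >= A_total ",
           "(one bound ATP per actin); supply a custom init otherwise")
    }
    init <- mixture_state(A = 0, AT = A_total, AS = 0,
                          T = T_total - A_total, S = S_total)
  } else {
    stopifnot(inherits(init, "mixture_state"))
    tot <- c(init[["A"]] + init[["AT"]] + init[["AS"]],
             init[["T"]] + init[["AT"]],
             init[["S"]] + init[["AS"]])
    want <- c(A_total, T_total, S_total)
    if (any(abs(tot - want) > 1e-9 * pmax(want, 1))) {
      stop("custom init is inconsistent with the stated totals")
    }
  }
  structure(list(A_total = A_total, T_total = T_total, S_total = S_total,
                 duration = duration, dt = dt, chase = chase,
                 scenario = scenario, init = init),
            class = "exchange_experiment")
}

#' @export
print.exchange_experiment <- function(x, ...) {
  cat(sprintf("Exchange experiment: %g uM actin, %g uM ATP, %g uM label\n",
              x$A_total, x$T_total, x$S_total))
  cat(sprintf("  duration %g s sampled every %g s; scenario '%s' (x%g)\n",
              x$duration, x$dt, x$scenario$label,
              x$scenario$exchange_multiplier))
  if (!is.null(x$chase)) {
    cat(sprintf("  ATP chase: +%g uM free ATP at t = %g s\n",
                x$chase$T_add, x$chase$time))
  }
  invisible(x)
}

# deSolve derivative function, parameters as a named vector
.exchange_deriv <- function(t, y, parms) {
  dAT <- parms[["k_on_T"]] * y[["A"]] * y[["T"]] - parms[["k_off_T"]] * y[["AT"]]
  dAS <- parms[["k_on_S"]] * y[["A"]] * y[["S"]] - parms[["k_off_S"]] * y[["AS"]]
  list(c(-(dAT + dAS), dAT, dAS, -dAT, -dAS))
}

.integrate_segment <- function(y0, times, rates, rtol, atol) {
  if (length(times) == 1L) {
    return(matrix(y0, nrow = 1, dimnames = list(NULL, names(y0))))
  }
  out <- deSolve::lsoda(y = y0, times = times, func = .exchange_deriv,
                        parms = unclass(rates), rtol = rtol, atol = atol,
                        maxsteps = 100000L)
  if (attr(out, "istate")[1L] < 0) {
    stop("ODE integration failed for this exchange condition")
  }
  out[, c("A", "AT", "AS", "T", "S"), drop = FALSE]
}

#' Simulate a nucleotide-exchange time course
#'
#' Integrates the mass-action rate equations of the competitive exchange
#' scheme over the experiment's sampling grid with a stiff-capable solver
#' (\code{deSolve::lsoda}). The experiment's scenario multiplier is applied
#' to the rates before integration, and an ATP chase, if present, is a step
#' increase of free ATP at the chase time (added volume treated as
#' negligible).
#'
#' @param experiment an \code{"exchange_experiment"}.
#' @param rates a \code{"rate_constants"} object (baseline; the scenario in
#'   \code{experiment} is applied on top).
#' @param times optional explicit sampling times (s), strictly increasing
#'   from 0; defaults to the experiment's regular grid
#'   \code{seq(0, duration, by = dt)}.
#' @param rtol,atol solver tolerances; defaults 1e-10 (relative) and
#'   1e-12 uM (absolute) keep the conservation sums good to better than one
#'   part in 1e9.
#' @return A \code{"timecourse"} of kind \code{"state"}: a data frame with
#'   columns \code{time, A, AT, AS, T, S} (s and uM).
#' @seealso [competitive_equilibrium()] for the analytic long-time limit.
#' @export
simulate_exchange <- function(experiment, rates, times = NULL,
                              rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(experiment, "exchange_experiment"),
            inherits(rates, "rate_constants"))
  rates <- apply_scenario(rates, experiment$scenario)
  if (is.null(times)) {
    grid <- seq(0, experiment$duration, by = experiment$dt)
    if (grid[length(grid)] < experiment$duration) {
      grid <- c(grid, experiment$duration)
    }
  } else {
    if (times[1L] != 0 || any(diff(times) <= 0)) {
      stop("times must be strictly increasing and start at 0")
    }
    grid <- times
  }
  y0 <- unclass(experiment$init)

  if (is.null(experiment$chase)) {
    traj <- .integrate_segment(y0, grid, rates, rtol, atol)
    times <- grid
  } else {
    tc <- experiment$chase$time
    t1 <- sort(unique(c(grid[grid < tc], tc)))
    t2 <- sort(unique(c(tc, grid[grid >= tc])))
    seg1 <- .integrate_segment(y0, t1, rates, rtol, atol)
    y_chase <- seg1[nrow(seg1), ]
    y_chase[["T"]] <- y_chase[["T"]] + experiment$chase$T_add
    seg2 <- .integrate_segment(y_chase, t2, rates, rtol, atol)
    # sample grid points before the chase from the first segment; a grid
    # point coinciding with the chase instant reports the post-addition state
    traj <- rbind(seg1[match(grid[grid < tc], t1), , drop = FALSE],
                  seg2[match(grid[grid >= tc], t2), , drop = FALSE])
    times <- grid
  }
  traj[traj < 0 & traj > -atol * 10] <- 0
  df <- data.frame(time = times, traj, check.names = FALSE)
  new_timecourse(df, kind = "state", experiment = experiment,
                 meta = list(rates = unclass(rates)))
}

#' Analytic competitive binding equilibrium
#'
#' Long-time limit of the two-ligand exchange scheme, computed independently
#' of the ODE path by root-finding on the coupled binding polynomials. At
#' equilibrium \code{AT = A * T_total / (Kd_T + A)} and
#' \code{AS = A * S_total / (Kd_S + A)}, so free actin \code{A} solves the
#' scalar conservation equation
#' \deqn{A + A T_{tot}/(K_{d,T} + A) + A S_{tot}/(K_{d,S} + A) = A_{tot},}
#' whose left side is strictly increasing in \code{A}; the root is bracketed
#' on \code{[0, A_total]} and located with \code{uniroot} at machine-level
#' tolerance.
#'
#' @param A_total,T_total,S_total totals in uM, each >= 0.
#' @param rates a \code{"rate_constants"} object.
#' @return A \code{"mixture_state"} at equilibrium.
#' @export
competitive_equilibrium <- function(A_total, T_total, S_total, rates) {
  stopifnot(inherits(rates, "rate_constants"))
  if (any(c(A_total, T_total, S_total) < 0)) stop("totals must be >= 0")
  if (A_total == 0) {
    return(mixture_state(A = 0, AT = 0, AS = 0, T = T_total, S = S_total))
  }
  kds <- kd(rates)
  KT <- kds[["Kd_T"]]; KS <- kds[["Kd_S"]]
  f <- function(A) {
    A + A * T_total / (KT + A) + A * S_total / (KS + A) - A_total
  }
  if (T_total == 0 && S_total == 0) {
    A <- A_total
  } else {
    A <- stats::uniroot(f, lower = 0, upper = A_total,
                        tol = .Machine$double.eps^0.9,
                        maxiter = 10000L)$root
    # f is steep near the root when ligands are in excess; polish with a few
    # Newton steps so the residual reaches rounding level
    fp <- function(A) {
      1 + T_total * KT / (KT + A)^2 + S_total * KS / (KS + A)^2
    }
    for (i in 1:5) {
      step <- f(A) / fp(A)
      A_new <- min(max(A - step, 0), A_total)
      if (A_new == A) break
      A <- A_new
    }
  }
  AT <- A * T_total / (KT + A)
  AS <- A * S_total / (KS + A)
  # polish free actin so conservation of actin is exact to rounding
  A <- max(A_total - AT - AS, 0)
  mixture_state(A = A, AT = AT, AS = AS,
                T = max(T_total - AT, 0), S = max(S_total - AS, 0))
}
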