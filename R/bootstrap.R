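#' Residual-resampling bootstrap confidence intervals
#'
#' Uncertainty on fitted parameters by residual resampling: centred fit
#' residuals are resampled with replacement onto the fitted values, the
#' model is refit to each replicate starting from the point estimates, and
#' percentile intervals are formed at the requested level. Fully seeded and
#' reproducible: the same seed and configuration give bit-identical
#' intervals.
#'
#' Replicate fits that fail are dropped and counted; if more than 20% of
#' replicates fail the procedure aborts with diagnostics.
#'
#' @param fit a converged \code{"titration_fit"} or \code{"exchange_fit"}.
#' @param n_replicates number of bootstrap replicates (>= 100).
#' @param seed integer seed (required).
#' @param level confidence level, default 0.95.
#' @param ... unused.
#' @return An object of class \code{"bootstrap_ci"}: a matrix with one row
#'   per free parameter and columns \code{estimate, lower, upper}, with
#'   attributes \code{level}, \code{n_replicates}, \code{seed},
#'   \code{n_failed}, and \code{replicates} (the replicate parameter
#'   matrix).
#' @export
bootstrap_ci <- function(fit, n_replicates = 200, seed, level = 0.95, ...) {
  UseMethod("bootstrap_ci")
}

.bootstrap_engine <- function(estimates, fitted_vals, residuals, refit,
                              n_replicates, seed, level) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required for reproducible bootstrap intervals")
  }
  if (n_replicates < 100) stop("n_replicates must be >= 100")
  res <- residuals - mean(residuals)
  n <- length(res)
  set.seed(as.integer(seed))
  draws <- matrix(sample.int(n, n * n_replicates, replace = TRUE),
                  nrow = n)
  reps <- matrix(NA_real_, nrow = n_replicates, ncol = length(estimates),
                 dimnames = list(NULL, names(estimates)))
  failures <- character(0)
  for (b in seq_len(n_replicates)) {
    y_star <- fitted_vals + res[draws[, b]]
    out <- tryCatch(refit(y_star), error = function(e) e)
    if (inherits(out, "error")) {
      failures <- c(failures, conditionMessage(out))
    } else {
      reps[b, ] <- out[names(estimates)]
    }
  }
  n_failed <- length(failures)
  if (n_failed > 0.2 * n_replicates) {
    stop(sprintf("bootstrap aborted: %d of %d replicate fits failed; first: %s",
                 n_failed, n_replicates, failures[1L]))
  }
  ok <- stats::complete.cases(reps)
  alpha <- (1 - level) / 2
  ci <- t(apply(reps[ok, , drop = FALSE], 2, stats::quantile,
                probs = c(alpha, 1 - alpha), names = FALSE, type = 7))
  out <- cbind(estimate = estimates, lower = ci[, 1], upper = ci[, 2])
  structure(out, class = c("bootstrap_ci", class(out)),
            level = level, n_replicates = n_replicates, seed = seed,
            n_failed = n_failed, replicates = reps[ok, , drop = FALSE])
}

#' @rdname bootstrap_ci
#' @export
bootstrap_ci.titration_fit <- function(fit, n_replicates = 200, seed,
                                       level = 0.95, ...) {
  g <- fit$data$g_actin
  est <- fit$coefficients
  refit <- function(y_star) {
    f <- titration_fit(data.frame(g_actin = g, r = y_star),
                       start = as.list(est), ABP_total = fit$ABP_total)
    f$coefficients
  }
  .bootstrap_engine(est, fitted(fit), residuals(fit), refit,
                    n_replicates, seed, level)
}

#' @rdname bootstrap_ci
#' @export
bootstrap_ci.exchange_fit <- function(fit, n_replicates = 200, seed,
                                      level = 0.95, ...) {
  est <- fit$coefficients[fit$free]
  datasets <- fit$datasets
  npts <- fit$n_points
  refit <- function(y_star) {
    # redistribute the resampled response over the per-dataset blocks
    off <- 0L
    data_star <- vector("list", length(datasets))
    for (i in seq_along(datasets)) {
      d <- datasets[[i]]
      bound <- y_star[off + seq_len(npts[i])]
      off <- off + npts[i]
      data_star[[i]] <- new_timecourse(
        data.frame(time = d$time, bound = bound,
                   free = d$experiment$S_total - bound),
        kind = "bound_concentration", experiment = d$experiment)
    }
    f <- suppressWarnings(
      exchange_fit(data_star, fixed = fit$fixed, start = est))
    f$coefficients[fit$free]
  }
  .bootstrap_engine(est, fit$fitted, fit$residuals, refit,
                    n_replicates, seed, level)
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf(
    "Residual bootstrap (%d replicates, %d failed, seed %s, %.0f%% CI)\n",
    attr(x, "n_replicates"), attr(x, "n_failed"),
    format(attr(x, "seed")), 100 * attr(x, "level")))
  print(round(unclass(x)[, , drop = FALSE], 6))
  invisible(x)
}
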