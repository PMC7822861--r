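#' Time-course container
#'
#' A \code{"timecourse"} is a data frame with a \code{time} column (seconds,
#' strictly increasing from 0) plus value columns, tagged by \code{kind}:
#' \describe{
#'   \item{\code{"state"}}{full mixture state, columns
#'     \code{A, AT, AS, T, S} (uM).}
#'   \item{\code{"anisotropy"}}{single observable column \code{r}.}
#'   \item{\code{"bound_concentration"}}{columns \code{bound} and \code{free}
#'     (uM of labelled analogue).}
#' }
#' The attached \code{experiment} (an \code{"exchange_experiment"}) and
#' \code{meta} list carry everything needed to refit the trace: totals,
#' calibration, scenario, noise seed.
#'
#' @param df data frame with a \code{time} column and the value columns for
#'   \code{kind}.
#' @param kind one of \code{"state"}, \code{"anisotropy"},
#'   \code{"bound_concentration"}.
#' @param experiment optional \code{"exchange_experiment"} describing the
#'   condition.
#' @param meta named list of free-form metadata (calibration, seed, ...).
#' @return The data frame with class \code{c("timecourse", "data.frame")}.
#' @export
new_timecourse <- function(df, kind = c("state", "anisotropy",
                                        "bound_concentration"),
                           experiment = NULL, meta = list()) {
  kind <- match.arg(kind)
  if (!is.data.frame(df) || !"time" %in% names(df)) {
    stop("df must be a data frame with a 'time' column")
  }
  tt <- df$time
  if (length(tt) < 1L || tt[1L] != 0 || any(diff(tt) <= 0)) {
    stop("times must be strictly increasing and start at 0")
  }
  need <- switch(kind,
                 state = c("A", "AT", "AS", "T", "S"),
                 anisotropy = "r",
                 bound_concentration = c("bound", "free"))
  if (!all(need %in% names(df))) {
    stop(sprintf("kind '%s' requires columns: %s", kind,
                 paste(need, collapse = ", ")))
  }
  rownames(df) <- NULL
  structure(df, kind = kind, experiment = experiment, meta = meta,
            class = c("timecourse", "data.frame"))
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("Time course (kind = %s): %d samples over %g s\n",
              attr(x, "kind"), nrow(x), x$time[nrow(x)]))
  ex <- attr(x, "experiment")
  if (!is.null(ex)) {
    cat(sprintf("  condition: %g uM actin, %g uM ATP, %g uM label (%s)\n",
                ex$A_total, ex$T_total, ex$S_total, ex$scenario$label))
  }
  print(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat(sprintf("  ... %d more rows\n", nrow(x) - 4L))
  invisible(x)
}

#' Kind tag of a time course
#' @param tc a \code{"timecourse"}.
#' @return Character scalar.
#' @export
timecourse_kind <- function(tc) {
  stopifnot(inherits(tc, "timecourse"))
  attr(tc, "kind")
}

#' @export
plot.timecourse <- function(x, ...) {
  kind <- attr(x, "kind")
  if (kind == "state") {
    graphics::matplot(x$time, as.matrix(x[c("A", "AT", "AS", "T", "S")]),
                      type = "l", lty = 1, xlab = "time (s)",
                      ylab = "concentration (uM)", ...)
    graphics::legend("right", legend = c("A", "AT", "AS", "T", "S"),
                     col = 1:5, lty = 1, bty = "n")
  } else if (kind == "anisotropy") {
    graphics::plot(x$time, x$r, type = "l", xlab = "time (s)",
                   ylab = "anisotropy r", ...)
  } else {
    graphics::plot(x$time, x$bound, type = "l", xlab = "time (s)",
                   ylab = "bound analogue (uM)", ...)
  }
  invisible(x)
}
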