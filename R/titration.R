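#' Titration parameters for a labelled actin-binding protein
#'
#' Parameters of the quadratic binding isotherm in anisotropy space:
#' the dissociation constant \code{Kd} (uM) of the labelled ABP for G-actin,
#' and the anisotropy extremes \code{r_min} (unbound labelled ABP) and
#' \code{r_max} (actin-bound labelled ABP).
#'
#' @param Kd dissociation constant, uM, > 0.
#' @param r_min,r_max anisotropy of the unbound / bound labelled protein;
#'   \code{r_min < r_max}.
#' @return An object of class \code{"titration_params"}.
#' @export
titration_params <- function(Kd, r_min, r_max) {
  if (!is.numeric(Kd) || length(Kd) != 1L || Kd <= 0) {
    stop("Kd must be a single positive number")
  }
  if (r_min >= r_max) stop("need r_min < r_max")
  structure(list(Kd = Kd, r_min = r_min, r_max = r_max),
            class = "titration_params")
}

#' @export
print.titration_params <- function(x, ...) {
  cat(sprintf("Titration parameters: Kd = %g uM, r_min = %g, r_max = %g\n",
              x$Kd, x$r_min, x$r_max))
  invisible(x)
}

#' Quadratic binding isotherm in anisotropy space
#'
#' Exact closed-form anisotropy of a fixed total concentration of labelled
#' ABP titrated with G-actin, without the free-ligand approximation:
#' \deqn{r = r_{min} + (r_{max} - r_{min})
#'   \frac{K_d + G + P - \sqrt{(K_d + G + P)^2 - 4 G P}}{2 P},}
#' where \eqn{G} is total G-actin and \eqn{P} total labelled ABP (uM). The
#' bracketed bound fraction lies in [0, 1]: it is 0 at \eqn{G = 0} and tends
#' to 1 as \eqn{G \to \infty}.
#'
#' @param params a \code{"titration_params"} object (or a list with
#'   \code{Kd, r_min, r_max}).
#' @param G_total total G-actin concentration(s), uM, >= 0 (vectorized).
#' @param ABP_total total labelled ABP concentration, uM, > 0.
#' @return Anisotropy value(s).
#' @export
titration_model_eval <- function(params, G_total, ABP_total) {
  if (ABP_total <= 0) stop("ABP_total must be > 0")
  if (any(G_total < 0)) stop("G_total must be >= 0")
  Kd <- params$Kd; r_min <- params$r_min; r_max <- params$r_max
  s <- Kd + G_total + ABP_total
  rad <- s^2 - 4 * G_total * ABP_total
  if (any(rad < 0)) stop("internal error: negative radicand in isotherm")
  frac <- (s - sqrt(rad)) / (2 * ABP_total)
  r_min + (r_max - r_min) * frac
}

#' Titration dataset of a labelled ABP against G-actin
#'
#' @param G_totals total G-actin concentrations, uM, >= 0.
#' @param r observed anisotropy, same length as \code{G_totals}.
#' @param ABP_total fixed total labelled ABP concentration, uM, > 0.
#' @param meta optional named metadata list (generating parameters, seed).
#' @return A data frame of class \code{"titration"} with columns
#'   \code{g_actin} and \code{r} and attributes \code{ABP_total},
#'   \code{meta}. Warns when the design is weak for Kd estimation (fewer
#'   than 5 distinct actin concentrations, or no point near zero actin).
#' @export
titration_dataset <- function(G_totals, r, ABP_total, meta = list()) {
  if (length(G_totals) != length(r)) {
    stop("G_totals and r must have the same length")
  }
  if (any(G_totals < 0)) stop("G_totals must be >= 0")
  if (ABP_total <= 0) stop("ABP_total must be > 0")
  gu <- unique(G_totals)
  if (length(gu) < 5L) {
    warning("fewer than 5 distinct G-actin concentrations; ",
            "Kd may be poorly determined")
  } else if (min(gu) > 0.05 * max(gu)) {
    warning("no titration point near zero G-actin; ",
            "r_min may be poorly determined")
  }
  structure(data.frame(g_actin = G_totals, r = r),
            ABP_total = ABP_total, meta = meta,
            class = c("titration", "data.frame"))
}

#' @export
print.titration <- function(x, ...) {
  cat(sprintf("Titration: %g uM labelled ABP vs %d G-actin concentrations\n",
              attr(x, "ABP_total"), nrow(x)))
  print.data.frame(utils::head(x, 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Least-squares fit of the quadratic binding isotherm
#'
#' Estimates \code{(Kd, r_min, r_max)} from a titration by nonlinear least
#' squares (Levenberg-Marquardt, \code{minpack.lm::nlsLM}, with \code{Kd}
#' bounded below by zero). Default starting values are taken from the data:
#' \code{r_min} from the anisotropy at the smallest actin concentration,
#' \code{r_max} from the largest, \code{Kd} from the actin concentration
#' nearest the half-range anisotropy.
#'
#' @param data a \code{"titration"} (see [titration_dataset()]), or a data
#'   frame with columns \code{g_actin} and \code{r} plus \code{ABP_total}
#'   given separately.
#' @param start optional \code{"titration_params"} (or list) of starting
#'   values.
#' @param ABP_total total labelled ABP, uM; defaults to the dataset
#'   attribute.
#' @return An object of class \code{"titration_fit"} with components
#'   \code{params} (\code{"titration_params"}), \code{coefficients},
#'   \code{rss}, \code{converged}, \code{niter}, \code{data}, \code{fit}
#'   (the underlying \code{nls} object).
#' @examples
#' tp <- titration_params(Kd = 2.1, r_min = 0.10, r_max = 0.30)
#' d <- synth_titration(tp, ABP_total = 0.5, G_grid = seq(0, 20, length = 12))
#' coef(titration_fit(d))
#' @export
titration_fit <- function(data, start = NULL, ABP_total = NULL) {
  if (is.null(ABP_total)) ABP_total <- attr(data, "ABP_total")
  if (is.null(ABP_total)) stop("ABP_total is required")
  if (!all(c("g_actin", "r") %in% names(data))) {
    stop("data must have columns 'g_actin' and 'r'")
  }
  g <- data$g_actin; r <- data$r
  span <- diff(range(r))
  if (span < 1e-6) {
    stop("unidentifiable Kd: anisotropy is flat across the titration ",
         "(range ", signif(span, 3), ")")
  }
  if (is.null(start)) {
    r0 <- r[which.min(g)]; r1 <- r[which.max(g)]
    half <- (r0 + r1) / 2
    Kd0 <- g[which.min(abs(r - half))]
    if (Kd0 <= 0) Kd0 <- stats::median(g[g > 0])
    start <- list(Kd = Kd0, r_min = min(r0, r1), r_max = max(r0, r1))
  }
  if (inherits(start, "titration_params")) start <- unclass(start)
  fit <- minpack.lm::nlsLM(
    r ~ r_min + (r_max - r_min) *
      ((Kd + g_actin + ABP_total -
          sqrt((Kd + g_actin + ABP_total)^2 -
                 4 * g_actin * ABP_total)) / (2 * ABP_total)),
    data = data.frame(g_actin = g, r = r),
    start = start[c("Kd", "r_min", "r_max")],
    lower = c(Kd = 1e-9, r_min = -0.5, r_max = -0.5),
    control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                         maxiter = 200))
  cf <- stats::coef(fit)
  conv <- fit$convInfo$isConv
  if (!isTRUE(conv)) {
    stop("titration fit did not converge: ", fit$convInfo$stopMessage)
  }
  if (max(g) < 3 * cf[["Kd"]]) {
    warning("titration does not reach 3x the fitted Kd; ",
            "the estimate may be extrapolated")
  }
  structure(list(params = titration_params(cf[["Kd"]], cf[["r_min"]],
                                           cf[["r_max"]]),
                 coefficients = cf,
                 rss = sum(stats::resid(fit)^2),
                 converged = TRUE,
                 niter = fit$convInfo$finIter,
                 ABP_total = ABP_total,
                 data = data.frame(g_actin = g, r = r),
                 fit = fit),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat("Quadratic-isotherm titration fit\n")
  cat(sprintf("  ABP_total = %g uM, n = %d points, RSS = %.4g\n",
              x$ABP_total, nrow(x$data), x$rss))
  cat(sprintf("  Kd = %.4g uM, r_min = %.4g, r_max = %.4g (%d iterations)\n",
              x$coefficients[["Kd"]], x$coefficients[["r_min"]],
              x$coefficients[["r_max"]], x$niter))
  invisible(x)
}

#' @export
coef.titration_fit <- function(object, ...) object$coefficients

#' @export
residuals.titration_fit <- function(object, ...) {
  object$data$r - fitted(object)
}

#' @export
fitted.titration_fit <- function(object, ...) {
  titration_model_eval(object$params, object$data$g_actin, object$ABP_total)
}

#' @export
predict.titration_fit <- function(object, G_total = NULL, ...) {
  if (is.null(G_total)) G_total <- object$data$g_actin
  titration_model_eval(object$params, G_total, object$ABP_total)
}

#' @export
summary.titration_fit <- function(object, ...) {
  s <- summary(object$fit)
  out <- list(coefficients = s$coefficients, rss = object$rss,
              sigma = s$sigma, n = nrow(object$data),
              ABP_total = object$ABP_total)
  class(out) <- "summary.titration_fit"
  out
}

#' @export
print.summary.titration_fit <- function(x, ...) {
  cat(sprintf("Titration fit (ABP_total = %g uM, n = %d, sigma = %.3g)\n",
              x$ABP_total, x$n, x$sigma))
  print(x$coefficients)
  invisible(x)
}

#' @export
plot.titration_fit <- function(x, ...) {
  graphics::plot(x$data$g_actin, x$data$r, pch = 16,
                 xlab = "G-actin (uM)", ylab = "anisotropy r", ...)
  gg <- seq(0, max(x$data$g_actin), length.out = 200)
  graphics::lines(gg, predict(x, gg), col = 2, lwd = 2)
  invisible(x)
}
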