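#' Read and write time-course CSV files
#'
#' The package's CSV dialect is UTF-8, comma-separated, "." decimal, with
#' leading metadata lines of the form \code{# key=value} followed by a
#' header row. Three layouts are used, keyed by the header:
#' \describe{
#'   \item{state}{\code{time_s,A_uM,AT_uM,AS_uM,T_uM,S_uM}}
#'   \item{anisotropy}{\code{time_s,anisotropy}, metadata including
#'     \code{S_total_uM}, \code{r_MIN}, \code{r_MAX}, condition and seed}
#'   \item{bound concentration}{\code{time_s,bound_uM,free_uM}}
#' }
#' Values round-trip at full double precision; metadata keys written are
#' recovered on read. Malformed metadata, missing columns or non-monotone
#' time are rejected with the offending line number.
#'
#' @param tc a \code{"timecourse"}.
#' @param path file path.
#' @return \code{write_timecourse} returns \code{path} invisibly;
#'   \code{read_timecourse} returns a \code{"timecourse"} with the
#'   experiment and calibration rebuilt from metadata where present.
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "timecourse"))
  kind <- timecourse_kind(tc)
  ex <- attr(tc, "experiment")
  meta <- attr(tc, "meta")
  kv <- c(kind = kind)
  if (!is.null(ex)) {
    kv <- c(kv,
            A_total_uM = .num17(ex$A_total), T_total_uM = .num17(ex$T_total),
            S_total_uM = .num17(ex$S_total),
            duration_s = .num17(ex$duration), dt_s = .num17(ex$dt),
            scenario = ex$scenario$label,
            exchange_multiplier = .num17(ex$scenario$exchange_multiplier))
    if (!is.null(ex$chase)) {
      kv <- c(kv, chase_time_s = .num17(ex$chase$time),
              chase_T_add_uM = .num17(ex$chase$T_add))
    }
  }
  cal <- meta$calibration
  if (!is.null(cal)) {
    kv <- c(kv, r_MIN = .num17(cal$r_min), r_MAX = .num17(cal$r_max),
            calibration_method = cal$method)
  }
  if (!is.null(meta$noise_sd)) kv <- c(kv, noise_sd = .num17(meta$noise_sd))
  if (!is.null(meta$seed)) kv <- c(kv, seed = format(meta$seed))
  if (!is.null(meta$assumption)) kv <- c(kv, assumption = meta$assumption)

  header <- switch(kind,
                   state = "time_s,A_uM,AT_uM,AS_uM,T_uM,S_uM",
                   anisotropy = "time_s,anisotropy",
                   bound_concentration = "time_s,bound_uM,free_uM")
  cols <- switch(kind,
                 state = c("time", "A", "AT", "AS", "T", "S"),
                 anisotropy = c("time", "r"),
                 bound_concentration = c("time", "bound", "free"))
  body <- do.call(paste, c(lapply(as.data.frame(tc)[cols], .num17),
                           sep = ","))
  writeLines(c(sprintf("# %s=%s", names(kv), kv), header, body),
             con = path, useBytes = TRUE)
  invisible(path)
}

.num17 <- function(x) sprintf("%.17g", x)

.parse_metadata <- function(lines) {
  meta_lines <- grep("^#", lines)
  kv <- list()
  for (i in meta_lines) {
    s <- sub("^#\\s*", "", lines[i])
    if (!grepl("=", s, fixed = TRUE)) {
      stop(sprintf("malformed metadata at line %d: '%s' (expected key=value)",
                   i, lines[i]))
    }
    key <- sub("=.*$", "", s)
    val <- sub("^[^=]*=", "", s)
    kv[[trimws(key)]] <- trimws(val)
  }
  list(meta = kv, n_skip = length(meta_lines))
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  pm <- .parse_metadata(lines)
  kv <- pm$meta
  body <- if (pm$n_skip) lines[-seq_len(pm$n_skip)] else lines
  if (!length(body)) stop("no header row found in ", path)
  header <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
  layouts <- list(
    state = c("time_s", "A_uM", "AT_uM", "AS_uM", "T_uM", "S_uM"),
    anisotropy = c("time_s", "anisotropy"),
    bound_concentration = c("time_s", "bound_uM", "free_uM"))
  kind <- NA_character_
  for (k in names(layouts)) {
    if (identical(header, layouts[[k]])) kind <- k
  }
  if (is.na(kind)) {
    stop(sprintf("line %d: unrecognized column header '%s'",
                 pm$n_skip + 1L, body[1L]))
  }
  df <- utils::read.csv(text = body, colClasses = "numeric")
  names(df) <- switch(kind,
                      state = c("time", "A", "AT", "AS", "T", "S"),
                      anisotropy = c("time", "r"),
                      bound_concentration = c("time", "bound", "free"))
  if (any(diff(df$time) <= 0) || df$time[1L] != 0) {
    bad <- which(c(FALSE, diff(df$time) <= 0))[1L]
    stop(sprintf("line %d: time values must be strictly increasing from 0",
                 pm$n_skip + 1L + (if (is.na(bad)) 1L else bad)))
  }

  num <- function(key) if (is.null(kv[[key]])) NULL else as.numeric(kv[[key]])
  ex <- NULL
  if (!is.null(num("A_total_uM"))) {
    chase <- if (!is.null(num("chase_time_s"))) {
      list(time = num("chase_time_s"), T_add = num("chase_T_add_uM"))
    }
    scen <- scenario_modifiers(
      exchange_multiplier = if (is.null(num("exchange_multiplier"))) 1 else
        num("exchange_multiplier"),
      label = if (is.null(kv$scenario)) "unknown" else kv$scenario)
    ex <- exchange_experiment(A_total = num("A_total_uM"),
                              S_total = num("S_total_uM"),
                              T_total = num("T_total_uM"),
                              duration = num("duration_s"),
                              dt = num("dt_s"),
                              chase = chase, scenario = scen)
  }
  meta <- list()
  if (!is.null(num("r_MIN")) && !is.null(num("r_MAX"))) {
    method <- if (is.null(kv$calibration_method)) "synthetic" else
      kv$calibration_method
    meta$calibration <- anisotropy_calibration(num("r_MIN"), num("r_MAX"),
                                               method = method)
  }
  if (!is.null(num("noise_sd"))) meta$noise_sd <- num("noise_sd")
  if (!is.null(kv$seed)) meta$seed <- as.integer(kv$seed)
  if (!is.null(kv$assumption)) meta$assumption <- kv$assumption
  new_timecourse(df, kind = kind, experiment = ex, meta = meta)
}

#' Read and write titration CSV files
#'
#' Dialect: \code{# key=value} metadata including \code{abp_total_uM},
#' then header \code{g_actin_uM,anisotropy}.
#'
#' @param data a \code{"titration"} dataset.
#' @param path file path.
#' @return \code{write_titration} returns \code{path} invisibly;
#'   \code{read_titration} a \code{"titration"}.
#' @export
write_titration <- function(data, path) {
  stopifnot(inherits(data, "titration"))
  meta <- attr(data, "meta")
  kv <- c(abp_total_uM = .num17(attr(data, "ABP_total")))
  if (!is.null(meta$noise_sd)) kv <- c(kv, noise_sd = .num17(meta$noise_sd))
  if (!is.null(meta$seed)) kv <- c(kv, seed = format(meta$seed))
  body <- paste(.num17(data$g_actin), .num17(data$r), sep = ",")
  writeLines(c(sprintf("# %s=%s", names(kv), kv),
               "g_actin_uM,anisotropy", body), con = path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_titration
#' @export
read_titration <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  pm <- .parse_metadata(lines)
  body <- if (pm$n_skip) lines[-seq_len(pm$n_skip)] else lines
  if (!length(body) || !identical(strsplit(body[1L], ",")[[1L]],
                                  c("g_actin_uM", "anisotropy"))) {
    stop(sprintf("line %d: expected header 'g_actin_uM,anisotropy'",
                 pm$n_skip + 1L))
  }
  if (is.null(pm$meta$abp_total_uM)) {
    stop("missing required metadata key 'abp_total_uM'")
  }
  df <- utils::read.csv(text = body, colClasses = "numeric")
  suppressWarnings(
    titration_dataset(df$g_actin_uM, df$anisotropy,
                      ABP_total = as.numeric(pm$meta$abp_total_uM)))
}
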