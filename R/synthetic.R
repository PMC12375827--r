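# Synthetic two-arm trial generator. Emulates the shape of the trial inputs
# the pipeline consumes (per-subject PFS/OS with PFS <= OS, administrative
# censoring, digitized KM coordinates + numbers-at-risk) so every downstream
# stage is testable without external data.

#' Specification of one synthetic trial arm
#'
#' @param n Number of subjects.
#' @param median_pfs,median_os Target Kaplan-Meier medians in months;
#'   `0 < median_pfs <= median_os`. Generation calibrates the underlying
#'   distributions so the true medians equal these values exactly.
#' @param family Generating family for PFS times: `"exponential"` (default;
#'   fully determined by the median) or `"weibull"` (requires `shape`).
#'   Post-progression survival is exponential with its rate solved so the
#'   OS = PFS + post-progression sum has median `median_os`.
#' @param shape Weibull shape when `family = "weibull"`.
#' @param censor_time Administrative censoring time in months (default 30).
#' @param dropout_rate Fraction of subjects censored uniformly before
#'   `censor_time` (default 0.05).
#' @param seed Integer seed; generation is reproducible given the spec.
#' @param arm Arm label carried through to the generated records.
#' @return Object of class `arm_spec`.
#' @export
#' @examples
#' spec <- arm_spec(n = 533, median_pfs = 6.5, median_os = 12.7, seed = 42)
arm_spec <- function(n, median_pfs, median_os,
                     family = c("exponential", "weibull"), shape = NULL,
                     censor_time = 30, dropout_rate = 0.05,
                     seed = 42L, arm = "experimental") {
  family <- match.arg(family)
  if (n <= 0) stop("n must be > 0", call. = FALSE)
  if (!(median_pfs > 0 && median_pfs <= median_os))
    stop("need 0 < median_pfs <= median_os", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  if (family == "weibull" && (is.null(shape) || shape <= 0))
    stop("weibull generation needs a positive shape", call. = FALSE)
  structure(list(n = as.integer(n), median_pfs = median_pfs,
                 median_os = median_os, family = family, shape = shape,
                 censor_time = censor_time, dropout_rate = dropout_rate,
                 seed = as.integer(seed), arm = arm),
            class = "arm_spec")
}

#' Default arm specifications
#'
#' The experimental arm (n = 533) is calibrated to the published medians of
#' the pembrolizumab arm: OS 12.7 months, PFS 6.5 months. The trial
#' publication prints no control-arm medians; the shipped control defaults
#' (n = 536, OS 10.9, PFS 5.6 months) are synthetic calibration values
#' chosen only so that the experimental arm dominates on survival — they are
#' NOT sourced from the trial.
#'
#' @param seed Base seed; the control arm uses `seed + 1`.
#' @return Named list with `experimental` and `control` [arm_spec()]s.
#' @export
default_arm_specs <- function(seed = 42L) {
  list(
    experimental = arm_spec(n = 533, median_pfs = 6.5, median_os = 12.7,
                            seed = seed, arm = "experimental"),
    control = arm_spec(n = 536, median_pfs = 5.6, median_os = 10.9,
                       seed = seed + 1L, arm = "control")
  )
}

#' Per-subject survival records (pseudo-IPD)
#'
#' @param time Numeric vector of positive follow-up times (months).
#' @param event Integer vector; 1 = event observed, 0 = right-censored.
#' @param endpoint `"OS"` or `"PFS"`.
#' @param arm Arm label.
#' @return A data.frame of class `pseudo_ipd` with columns `time`, `event`
#'   and attributes `endpoint` and `arm`.
#' @export
pseudo_ipd <- function(time, event, endpoint = "OS", arm = "experimental") {
  if (length(time) == 0L) stop("empty IPD", call. = FALSE)
  if (any(time <= 0)) stop("all times must be > 0", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("events must be 0 or 1", call. = FALSE)
  if (length(time) != length(event)) stop("time/event length mismatch", call. = FALSE)
  out <- data.frame(time = as.numeric(time), event = as.integer(event))
  attr(out, "endpoint") <- match.arg(endpoint, c("OS", "PFS"))
  attr(out, "arm") <- arm
  class(out) <- c("pseudo_ipd", "data.frame")
  out
}

# Quantile function of the generating PFS family, parameterised by median.
.pfs_quantile <- function(u, spec) {
  switch(spec$family,
    exponential = stats::qexp(u, rate = log(2) / spec$median_pfs),
    weibull = stats::qweibull(u, shape = spec$shape,
                              scale = spec$median_pfs / log(2)^(1 / spec$shape))
  )
}

# Survival function of OS = PFS + Exp(rate_pps): S(t) = S_p(t) +
# int_0^t f_p(x) exp(-rate*(t-x)) dx, by closed form (exponential PFS,
# hypoexponential sum) or numeric quadrature (weibull PFS).
.os_survival <- function(t, spec, rate_pps) {
  if (spec$family == "exponential") {
    lp <- log(2) / spec$median_pfs
    ls <- rate_pps
    if (abs(lp - ls) < 1e-12) return((1 + lp * t) * exp(-lp * t))
    return((lp * exp(-ls * t) - ls * exp(-lp * t)) / (lp - ls))
  }
  shp <- spec$shape
  scl <- spec$median_pfs / log(2)^(1 / shp)
  sp <- stats::pweibull(t, shp, scl, lower.tail = FALSE)
  conv <- stats::integrate(function(x)
    stats::dweibull(x, shp, scl) * exp(-rate_pps * (t - x)),
    lower = 0, upper = t, rel.tol = 1e-10)$value
  sp + conv
}

# Rate of the exponential post-progression survival such that the OS sum
# has median spec$median_os. Unique root: as rate -> Inf the OS median ->
# PFS median; as rate -> 0 it -> Inf.
.solve_pps_rate <- function(spec) {
  target <- function(rate) .os_survival(spec$median_os, spec, rate) - 0.5
  if (spec$median_os <= spec$median_pfs * (1 + 1e-12)) return(1e8)
  stats::uniroot(target, lower = 1e-8, upper = 1e4, tol = 1e-12)$root
}

#' Draw i.i.d. survival times from a parametric family
#'
#' Sampling is by inverse-CDF transform of uniforms drawn under the given
#' seed, so for a fixed seed the draws are a monotone function of the
#' distribution parameters.
#'
#' @param family One of `"exponential"`, `"weibull"`, `"gamma"`,
#'   `"loglogistic"`, `"lognormal"`.
#' @param params Named numeric parameters: exponential `rate`; weibull
#'   `shape`, `scale`; gamma `shape`, `rate`; loglogistic `scale`, `shape`;
#'   lognormal `meanlog`, `sdlog`.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Numeric vector of `n` positive times.
#' @export
#' @examples
#' t <- sample_times("exponential", c(rate = log(2) / 12.7), 1000, seed = 1)
sample_times <- function(family, params, n, seed = 42L) {
  stopifnot(n > 0)
  family <- match.arg(family, SURV_FAMILIES)
  .check_params(family, params)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  u <- stats::runif(n)
  surv_quantile(family, params, u)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate both endpoints of one synthetic arm
#'
#' Per subject, a PFS time is drawn from the spec's family and an OS time is
#' constructed as PFS plus an exponential post-progression survival draw, so
#' `PFS <= OS` holds by construction. The post-progression rate is solved so
#' the true OS median equals `spec$median_os`. Each subject then receives a
#' single censoring time — `censor_time`, or uniform dropout before it with
#' probability `dropout_rate` — applied to both endpoints consistently.
#'
#' @param spec An [arm_spec()].
#' @return List with elements `pfs` and `os`, each a [pseudo_ipd()], plus
#'   attribute `latent` (data.frame of the uncensored latent times).
#' @export
#' @examples
#' arm <- generate_arm(arm_spec(200, 6.5, 12.7, seed = 7))
#' all(arm$pfs$time <= arm$os$time)
generate_arm <- function(spec) {
  stopifnot(inherits(spec, "arm_spec"))
  rate_pps <- .solve_pps_rate(spec)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  # fixed draw order => monotone response of times to the spec medians
  u_pfs <- stats::runif(spec$n)
  u_pps <- stats::runif(spec$n)
  u_drop <- stats::runif(spec$n)
  u_drop_t <- stats::runif(spec$n)
  t_pfs <- .pfs_quantile(u_pfs, spec)
  t_os <- t_pfs + stats::qexp(u_pps, rate = rate_pps)
  cens <- rep(spec$censor_time, spec$n)
  dropped <- u_drop < spec$dropout_rate
  cens[dropped] <- u_drop_t[dropped] * spec$censor_time
  obs_pfs <- pmin(t_pfs, cens)
  obs_os <- pmin(t_os, cens)
  out <- list(
    pfs = pseudo_ipd(obs_pfs, as.integer(t_pfs <= cens),
                     endpoint = "PFS", arm = spec$arm),
    os = pseudo_ipd(obs_os, as.integer(t_os <= cens),
                    endpoint = "OS", arm = spec$arm)
  )
  attr(out, "latent") <- data.frame(t_pfs = t_pfs, t_os = t_os, censor = cens)
  attr(out, "rate_pps") <- rate_pps
  out
}

#' Export a pseudo-IPD sample as a digitized KM curve plus risk table
#'
#' Stands in for manual digitization of a published figure: the Kaplan-Meier
#' curve of `ipd` is evaluated at the given grid of times (step-function
#' value, starting at 1) and numbers at risk are counted at every multiple
#' of `risk_interval` covering the follow-up span.
#'
#' @param ipd A [pseudo_ipd()].
#' @param grid Strictly increasing times (months), starting at >= 0. The
#'   default takes 31 points spanning the follow-up, merged with the
#'   risk-table tick times (a digitizer always clicks at the printed axis
#'   ticks, and downstream accuracy is assessed there).
#' @param risk_interval Spacing of the numbers-at-risk table in months.
#' @return List with `curve` (a [digitized_km()]) and `risk` (a
#'   [risk_table()]).
#' @export
export_digitized <- function(ipd, grid = NULL, risk_interval = 6) {
  stopifnot(inherits(ipd, "pseudo_ipd"))
  if (nrow(ipd) == 0L) stop("empty IPD", call. = FALSE)
  if (is.null(grid))
    grid <- sort(unique(c(seq(0, max(ipd$time), length.out = 31),
                          seq(0, max(ipd$time), by = risk_interval))))
  if (any(diff(grid) <= 0) || grid[1] < 0)
    stop("grid must be strictly increasing and start at >= 0", call. = FALSE)
  km <- kaplan_meier(ipd)
  surv <- km(grid)
  curve <- digitized_km(grid, surv, endpoint = attr(ipd, "endpoint"),
                        arm = attr(ipd, "arm"))
  rt_times <- seq(0, max(ipd$time), by = risk_interval)
  n_at_risk <- vapply(rt_times, function(t) sum(ipd$time >= t), integer(1))
  list(curve = curve, risk = risk_table(rt_times, n_at_risk))
}

#' Digitized Kaplan-Meier curve coordinates
#'
#' @param time Strictly increasing times (months), first >= 0.
#' @param survival Non-increasing survival probabilities; values slightly
#'   outside `[0, 1]` or slightly increasing (digitization noise up to
#'   0.005) are cleaned by clipping and an isotonic pass; larger violations
#'   are an error.
#' @param endpoint,arm Labels carried through the pipeline.
#' @return Object of class `digitized_km` with data.frame component
#'   `points`.
#' @export
digitized_km <- function(time, survival, endpoint = "OS", arm = "experimental") {
  if (length(time) == 0L) stop("empty curve", call. = FALSE)
  if (length(time) != length(survival)) stop("length mismatch", call. = FALSE)
  if (any(diff(time) <= 0) || time[1] < 0)
    stop("times must be strictly increasing and start at >= 0", call. = FALSE)
  if (any(survival > 1 + 0.005) || any(survival < -0.005) ||
      any(diff(survival) > 0.005))
    stop("survival coordinates violate monotone [0,1] beyond digitization tolerance",
         call. = FALSE)
  survival <- pmin(pmax(survival, 0), 1)
  survival <- rev(cummax(rev(survival)))  # isotonic non-increasing pass
  structure(list(points = data.frame(time = as.numeric(time),
                                     survival = as.numeric(survival)),
                 endpoint = endpoint, arm = arm),
            class = "digitized_km")
}

#' Numbers-at-risk table accompanying a published KM curve
#'
#' @param time Strictly increasing times starting at 0 (months).
#' @param n_at_risk Non-increasing subject counts; `n_at_risk[1]` is the arm
#'   size.
#' @return Object of class `risk_table` (a data.frame).
#' @export
risk_table <- function(time, n_at_risk) {
  if (length(time) == 0L) stop("empty risk table", call. = FALSE)
  if (time[1] != 0) stop("risk table must start at time 0", call. = FALSE)
  if (any(diff(time) <= 0)) stop("risk times must be strictly increasing", call. = FALSE)
  if (any(diff(n_at_risk) > 0)) stop("numbers at risk must be non-increasing", call. = FALSE)
  if (any(n_at_risk < 0)) stop("negative number at risk", call. = FALSE)
  out <- data.frame(time = as.numeric(time), n_at_risk = as.integer(n_at_risk))
  class(out) <- c("risk_table", "data.frame")
  out
}

#' @export
print.arm_spec <- function(x, ...) {
  cat(sprintf("<arm_spec> %s: n=%d, median PFS %.1f mo, median OS %.1f mo, %s\n",
              x$arm, x$n, x$median_pfs, x$median_os, x$family))
  cat(sprintf("  censoring: administrative at %.1f mo + %.0f%% uniform dropout; seed %d\n",
              x$censor_time, 100 * x$dropout_rate, x$seed))
  invisible(x)
}

# ---- CSV dialects shared with the reconstruction stage ----

#' Read/write the plain-text formats of the pipeline
#'
#' Digitized curves are CSVs with columns `time_months, survival`; risk
#' tables `time_months, n_at_risk`; pseudo-IPD `time_months, event`.
#'
#' @param x Object to write.
#' @param path File path.
#' @param endpoint,arm Labels attached on read.
#' @return Readers return the corresponding object; writers return `path`
#'   invisibly.
#' @name io_csv
NULL

#' @rdname io_csv
#' @export
write_digitized_csv <- function(x, path) {
  stopifnot(inherits(x, "digitized_km"))
  df <- data.frame(time_months = x$points$time, survival = x$points$survival)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io_csv
#' @export
read_digitized_csv <- function(path, endpoint = "OS", arm = "experimental") {
  df <- utils::read.csv(path)
  digitized_km(df$time_months, df$survival, endpoint = endpoint, arm = arm)
}

#' @rdname io_csv
#' @export
write_risk_table_csv <- function(x, path) {
  stopifnot(inherits(x, "risk_table"))
  utils::write.csv(data.frame(time_months = x$time, n_at_risk = x$n_at_risk),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname io_csv
#' @export
read_risk_table_csv <- function(path) {
  df <- utils::read.csv(path)
  risk_table(df$time_months, df$n_at_risk)
}

#' @rdname io_csv
#' @export
write_ipd_csv <- function(x, path) {
  stopifnot(inherits(x, "pseudo_ipd"))
  utils::write.csv(data.frame(time_months = x$time, event = x$event),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname io_csv
#' @export
read_ipd_csv <- function(path, endpoint = "OS", arm = "experimental") {
  df <- utils::read.csv(path)
  pseudo_ipd(df$time_months, df$event, endpoint = endpoint, arm = arm)
}
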