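# Kaplan-Meier estimation and pseudo-IPD reconstruction from digitized
# curve coordinates plus numbers-at-risk (interval-by-interval allocation
# in the style of Guyot et al. 2012).

#' Kaplan-Meier estimator
#'
#' Product-limit estimate of the survival function of a right-censored
#' sample, computed via [survival::survfit()]. The return value is a
#' right-continuous step function `S(t)` with `S(0) = 1` that drops only at
#' event times and stays constant after the last observed time.
#'
#' @param ipd A [pseudo_ipd()].
#' @return A function `S(t)` (vectorised). Attributes: `table`, a
#'   data.frame with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`; `n`, the sample size.
#' @export
#' @examples
#' km <- kaplan_meier(pseudo_ipd(c(1, 2), c(1, 1)))
#' km(c(0, 1, 2))  # 1.0 0.5 0.0
kaplan_meier <- function(ipd) {
  stopifnot(inherits(ipd, "pseudo_ipd"))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(ipd), conf.type = "none")
  tab <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  step <- stats::stepfun(tab$time, c(1, tab$survival), right = FALSE)
  f <- function(t) {
    if (any(t < 0)) stop("survival undefined for t < 0", call. = FALSE)
    step(t)
  }
  attr(f, "table") <- tab
  attr(f, "n") <- nrow(ipd)
  class(f) <- c("km_curve", "function")
  f
}

#' Median of a Kaplan-Meier curve
#'
#' Smallest observed time at which the estimated survival drops to 0.5 or
#' below (the standard KM median); `NA` when the curve never reaches 0.5.
#'
#' @param km A curve from [kaplan_meier()], or a [pseudo_ipd()].
#' @return Median time in the input's time unit (months), or `NA`.
#' @export
km_median <- function(km) {
  if (inherits(km, "pseudo_ipd")) km <- kaplan_meier(km)
  tab <- attr(km, "table")
  idx <- which(tab$survival <= 0.5 + 1e-12)
  if (!length(idx)) return(NA_real_)
  tab$time[idx[1L]]
}

#' Reconstruct pseudo-IPD from a digitized KM curve and risk table
#'
#' Interval-by-interval allocation: within each risk-table interval the
#' number censored is solved iteratively so that the running at-risk count
#' matches the printed number at risk at the next interval boundary, with
#' censoring times spread uniformly across the interval; event counts at
#' each digitized drop are chosen to match the digitized survival ratios.
#' An optional global event total is enforced exactly by converting the
#' latest event/censoring labels.
#'
#' @param curve A [digitized_km()].
#' @param risk A [risk_table()] whose intervals cover the curve's span, or
#'   `NULL` to fall back (with a warning) to a no-censoring assumption
#'   before the last plotted time; `arm_size` is then required.
#' @param total_events Optional integer; the output's event count equals it.
#' @param arm_size Initial number at risk, only used when `risk` is `NULL`.
#' @return A [pseudo_ipd()] whose KM curve matches `curve` within
#'   digitization tolerance and whose at-risk counts match `risk` at the
#'   table times where feasible.
#' @export
#' @examples
#' arm <- generate_arm(arm_spec(100, 6, 12, seed = 1))
#' dig <- export_digitized(arm$os, risk_interval = 6)
#' rec <- reconstruct_ipd(dig$curve, dig$risk)
reconstruct_ipd <- function(curve, risk, total_events = NULL, arm_size = NULL) {
  stopifnot(inherits(curve, "digitized_km"))
  t_k <- curve$points$time
  s_k <- curve$points$survival
  # the algorithm anchors at (0, 1)
  if (t_k[1] > 0) {
    t_k <- c(0, t_k)
    s_k <- c(1, s_k)
  }
  s_k[1] <- 1
  K <- length(t_k)

  if (is.null(risk)) {
    if (is.null(arm_size))
      stop("arm_size is required when no risk table is given", call. = FALSE)
    warning("no risk table supplied: assuming no censoring before the last ",
            "plotted time", call. = FALSE)
    risk <- risk_table(0, arm_size)
  }
  stopifnot(inherits(risk, "risk_table"))
  if (max(risk$time) > max(t_k) + 1e-9)
    stop("risk table extends beyond the digitized curve span", call. = FALSE)

  T_j <- risk$time
  n_j <- risk$n_at_risk
  J <- length(T_j)
  # click index ranges per risk interval [T_j, T_{j+1})
  lower <- vapply(T_j, function(T) which(t_k >= T - 1e-9)[1L], integer(1))
  upper <- c(lower[-1L] - 1L, K)
  if (any(is.na(lower)) || any(upper < lower))
    stop("risk intervals do not cover the curve: first violated interval ",
         which(is.na(lower) | upper < lower)[1L], call. = FALSE)

  d <- integer(K)        # events at click k
  cen <- integer(K)      # censorings in [t_k, t_{k+1})
  cen_times <- vector("list", K)
  n_hat <- numeric(K + 1L)
  n_hat[1] <- n_j[1]
  km_hat <- rep(1, K)

  run_interval <- function(j, n_censor_j, d, cen, cen_times, n_hat, km_hat, last) {
    lo <- lower[j]; up <- upper[j]
    # spread censor times uniformly over the interval
    span_lo <- t_k[lo]
    span_hi <- if (j < J) t_k[lower[j + 1L]] else t_k[K]
    cen[lo:up] <- 0L
    cen_times[lo:up] <- list(numeric(0))
    if (n_censor_j > 0 && span_hi > span_lo) {
      ct <- span_lo + seq_len(n_censor_j) * (span_hi - span_lo) / (n_censor_j + 1)
      bins <- findInterval(ct, t_k[lo:up] + 1e-12) + lo - 1L
      bins[bins < lo] <- lo
      for (k in lo:up) {
        sel <- ct[bins == k]
        cen[k] <- length(sel)
        cen_times[[k]] <- sel
      }
    }
    n_hat[lo] <- if (j == 1L) n_j[1] else n_hat[lo]
    for (k in lo:up) {
      if (k == 1L) {
        d[k] <- 0L
        km_hat[k] <- 1
      } else {
        ref <- km_hat[last]
        d[k] <- if (n_hat[k] > 0 && ref > 0)
          max(0L, min(round(n_hat[k] * (1 - s_k[k] / ref)), n_hat[k])) else 0L
        km_hat[k] <- if (n_hat[k] > 0) km_hat[last] * (1 - d[k] / n_hat[k]) else km_hat[last]
      }
      n_hat[k + 1L] <- n_hat[k] - d[k] - cen[k]
      if (d[k] > 0) last <- k
    }
    list(d = d, cen = cen, cen_times = cen_times, n_hat = n_hat,
         km_hat = km_hat, last = last)
  }

  last <- 1L
  for (j in seq_len(J)) {
    lo <- lower[j]
    if (j < J) {
      # initial guess for censorings in interval j from the survival ratio
      guess <- if (s_k[lo] > 0)
        round(n_hat[lo] * s_k[lower[j + 1L]] / s_k[lo]) - n_j[j + 1L] else 0
      n_censor_j <- max(0L, as.integer(guess))
    } else {
      n_censor_j <- 0L
    }
    res <- run_interval(j, n_censor_j, d, cen, cen_times, n_hat, km_hat, last)
    if (j < J) {
      for (iter in seq_len(60L)) {
        gap <- res$n_hat[lower[j + 1L]] - n_j[j + 1L]
        if (gap == 0) break
        n_censor_new <- n_censor_j + as.integer(gap)
        if (n_censor_new < 0L) n_censor_new <- 0L
        if (n_censor_new == n_censor_j) break
        n_censor_j <- n_censor_new
        res <- run_interval(j, n_censor_j, d, cen, cen_times, n_hat, km_hat, last)
      }
    }
    d <- res$d; cen <- res$cen; cen_times <- res$cen_times
    n_hat <- res$n_hat; km_hat <- res$km_hat; last <- res$last
  }

  # assemble per-subject records
  ev_times <- rep(t_k, times = d)
  cn_times <- unlist(cen_times)
  left_over <- n_hat[K + 1L]
  if (left_over > 0) cn_times <- c(cn_times, rep(t_k[K], left_over))

  if (!is.null(total_events)) {
    delta <- as.integer(total_events) - length(ev_times)
    if (delta > 0) {
      # promote the latest censorings to events
      cn_times <- sort(cn_times)
      take <- min(delta, length(cn_times))
      if (take < delta)
        stop("total_events exceeds the number of reconstructed subjects", call. = FALSE)
      idx <- seq.int(length(cn_times) - take + 1L, length(cn_times))
      ev_times <- c(ev_times, cn_times[idx])
      cn_times <- cn_times[-idx]
    } else if (delta < 0) {
      # demote the latest events to censorings
      ev_times <- sort(ev_times)
      idx <- seq.int(length(ev_times) + delta + 1L, length(ev_times))
      cn_times <- c(cn_times, ev_times[idx])
      ev_times <- ev_times[-idx]
    }
  }

  times <- c(ev_times, cn_times)
  events <- c(rep(1L, length(ev_times)), rep(0L, length(cn_times)))
  times[times <= 0] <- min(c(t_k[t_k > 0], 1e-6)) * 1e-3  # keep times positive
  ord <- order(times)
  pseudo_ipd(times[ord], events[ord], endpoint = curve$endpoint,
             arm = curve$arm)
}

#' Maximum absolute KM deviation of a reconstruction
#'
#' Quality metric for a reconstruction: the maximum over the digitized time
#' points of the absolute difference between the digitized survival and the
#' KM curve of the reconstructed sample.
#'
#' @param original A [digitized_km()].
#' @param recon A [pseudo_ipd()] (typically from [reconstruct_ipd()]).
#' @return A probability in `[0, 1]`.
#' @export
reconstruction_error <- function(original, recon) {
  stopifnot(inherits(original, "digitized_km"), inherits(recon, "pseudo_ipd"))
  km <- kaplan_meier(recon)
  max(abs(original$points$survival - km(original$points$time)))
}
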