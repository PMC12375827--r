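# Shared fixtures: analytic fits and a fast model context so engine and
# uncertainty tests do not need to run the full fitting pipeline.

make_fit <- function(family, params, n_obs = 100L, loglik = -100) {
  params <- unlist(params)
  opt_par <- log(params)
  if (family == "lognormal") opt_par["meanlog"] <- params["meanlog"]
  k <- length(params)
  structure(list(family = family, params = params, loglik = loglik,
                 n_params = k, n_obs = as.integer(n_obs),
                 aic = 2 * k - 2 * loglik, bic = k * log(n_obs) - 2 * loglik,
                 covariance = diag(1e-4, k), opt_par = opt_par),
            class = "parametric_fit")
}

exp_fit <- function(median) make_fit("exponential", c(rate = log(2) / median))

# exponential-curve context calibrated to the default synthetic medians
make_context <- function(config = builtin_configs()[["china"]],
                         settings = model_settings()) {
  cea_context(
    exp_fits = list(os = exp_fit(12.7), pfs = exp_fit(6.5)),
    ctl_fits = list(os = exp_fit(10.9), pfs = exp_fit(5.6)),
    config = config, settings = settings
  )
}

# product-limit estimate by brute-force risk-set iteration (independent of
# survival::survfit): S(t) = prod over event times <= t of (1 - d_i / n_i)
km_bruteforce <- function(time, event, at) {
  ev_times <- sort(unique(time[event == 1]))
  vapply(at, function(t) {
    s <- 1
    for (et in ev_times[ev_times <= t]) {
      n_risk <- sum(time >= et)
      d <- sum(time == et & event == 1)
      s <- s * (1 - d / n_risk)
    }
    s
  }, 0)
}
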