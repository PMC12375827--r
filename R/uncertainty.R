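# Deterministic and probabilistic sensitivity analysis, CEAC / ICE
# summaries, and pembrolizumab price-reduction scenario analysis.

#' Bundle a fitted model context
#'
#' Everything needed to (re)run the cost-effectiveness comparison: the four
#' survival fits and the economic configuration. Sensitivity and scenario
#' analyses perturb copies of this context.
#'
#' @param exp_fits,ctl_fits Lists with `os`/`pfs` [fit_parametric()]s.
#' @param config A [country_config()].
#' @param settings A [model_settings()].
#' @return Object of class `cea_context`.
#' @export
cea_context <- function(exp_fits, ctl_fits, config, settings = model_settings()) {
  structure(list(exp_fits = exp_fits, ctl_fits = ctl_fits,
                 config = config, settings = settings),
            class = "cea_context")
}

#' @rdname cea_context
#' @param ctx A `cea_context`.
#' @return `context_run()` returns the [run_cea()] result at the context's
#'   current parameter values.
#' @export
context_run <- function(ctx) {
  run_cea(ctx$exp_fits, ctx$ctl_fits, ctx$config, ctx$settings)
}

# ---- parameter addressing -------------------------------------------------

# Flat ids into the nested config: "drug_price.<drug>", "ae_cost.<ae>",
# "ae_prob_pem.<ae>", "ae_prob_chem.<ae>", or a scalar field name.
get_param <- function(config, id) {
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1L) return(unname(config[[id]]))
  unname(switch(parts[1],
    drug_price = config$drug_prices[[parts[2]]]$price,
    ae_cost = config$ae_costs[[parts[2]]],
    ae_prob_pem = config$ae_prob_pem[[parts[2]]],
    ae_prob_chem = config$ae_prob_chem[[parts[2]]],
    stop("unknown parameter id: ", id, call. = FALSE)
  ))
}

# Sensitivity analyses set slots directly (no cross-field revalidation:
# varying one parameter at a time may transiently break joint constraints
# such as u_pd <= u_pfs, which is standard DSA practice).
set_param <- function(config, id, value) {
  value <- unname(value)
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1L) {
    config[[id]] <- value
  } else {
    switch(parts[1],
      drug_price = config$drug_prices[[parts[2]]]$price <- value,
      ae_cost = config$ae_costs[[parts[2]]] <- value,
      ae_prob_pem = config$ae_prob_pem[[parts[2]]] <- value,
      ae_prob_chem = config$ae_prob_chem[[parts[2]]] <- value,
      stop("unknown parameter id: ", id, call. = FALSE)
    )
  }
  config
}

#' Default one-way sensitivity ranges
#'
#' Builds the +/-20% ranges of the base-case analysis for every uncertain
#' economic parameter: the six drug prices, the four AE costs, the four
#' per-cycle/one-time costs, both utilities and the eight AE
#' probabilities. Utilities and probabilities are capped at 1.
#'
#' @param config A [country_config()].
#' @param rel Relative half-width (default 0.2).
#' @return data.frame with columns `id`, `base`, `low`, `high`, `dist`
#'   (`"gamma"` for costs, `"beta"` for probabilities/utilities).
#' @export
dsa_default_ranges <- function(config, rel = 0.2) {
  ids_cost <- c(paste0("drug_price.", DRUG_NAMES),
                paste0("ae_cost.", AE_NAMES),
                "examination_cost", "administration_cost", "bsc_cost", "eol_cost")
  ids_beta <- c("u_pfs", "u_pd",
                paste0("ae_prob_pem.", AE_NAMES),
                paste0("ae_prob_chem.", AE_NAMES))
  ids <- c(ids_cost, ids_beta)
  base <- unname(vapply(ids, get_param, 0, config = config))
  low <- base * (1 - rel)
  high <- base * (1 + rel)
  dist <- c(rep("gamma", length(ids_cost)), rep("beta", length(ids_beta)))
  high[dist == "beta"] <- pmin(high[dist == "beta"], 1)
  data.frame(id = ids, base = base, low = low, high = high, dist = dist,
             row.names = NULL)
}

#' One-way deterministic sensitivity analysis
#'
#' Reruns the model once at each parameter's low and high value with all
#' other parameters at base, and reports the resulting ICER pair sorted by
#' bar width (tornado order). A model failure at one extreme is recorded
#' for that parameter rather than aborting the analysis.
#'
#' @param ctx A [cea_context()].
#' @param ranges data.frame with columns `id`, `base`, `low`, `high`
#'   (default [dsa_default_ranges()] of the context's config).
#' @return data.frame with columns `id`, `icer_low`, `icer_high`, `width`,
#'   `error`, sorted by decreasing `width`.
#' @export
one_way_dsa <- function(ctx, ranges = dsa_default_ranges(ctx$config)) {
  stopifnot(inherits(ctx, "cea_context"))
  if (any(!(ranges$low <= ranges$base & ranges$base <= ranges$high)))
    stop("invalid range: need low <= base <= high", call. = FALSE)
  eval_at <- function(id, value) {
    cfg <- set_param(ctx$config, id, value)
    run_cea(ctx$exp_fits, ctx$ctl_fits, cfg, ctx$settings)$icer
  }
  rows <- lapply(seq_len(nrow(ranges)), function(r) {
    id <- ranges$id[r]
    lo <- tryCatch(eval_at(id, ranges$low[r]), error = function(e) NA_real_)
    hi <- tryCatch(eval_at(id, ranges$high[r]), error = function(e) NA_real_)
    err <- if (anyNA(c(lo, hi))) "model failure at an extreme" else ""
    data.frame(id = id, icer_low = lo, icer_high = hi,
               width = abs(hi - lo), error = err)
  })
  out <- do.call(rbind, rows)
  out[order(-out$width), , drop = FALSE]
}

#' Moment-matching for PSA distributions
#'
#' `moments_to_gamma()` returns the (shape, scale) of the gamma
#' distribution with the given mean and standard deviation
#' (`shape = (mean/sd)^2`, `scale = sd^2/mean`); applied to cost
#' parameters. `moments_to_beta()` returns the (alpha, beta) matching the
#' moments of a beta distribution; applied to probabilities and utilities,
#' and only feasible when `sd^2 < mean (1 - mean)`.
#'
#' @param mean,sd Target first two moments (`mean > 0`, `sd > 0`; for the
#'   beta, `mean` in (0, 1)).
#' @return Named numeric: `c(shape, scale)` or `c(alpha, beta)`.
#' @export
#' @examples
#' moments_to_gamma(4, 2)    # shape 4, scale 1
#' moments_to_beta(0.5, 0.1) # alpha = beta = 12
moments_to_gamma <- function(mean, sd) {
  if (mean <= 0 || sd <= 0) stop("mean and sd must be > 0", call. = FALSE)
  c(shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' @rdname moments_to_gamma
#' @export
moments_to_beta <- function(mean, sd) {
  if (mean <= 0 || mean >= 1) stop("mean must be in (0, 1)", call. = FALSE)
  if (sd <= 0) stop("sd must be > 0", call. = FALSE)
  if (sd^2 >= mean * (1 - mean))
    stop("variance infeasible for beta", call. = FALSE)
  alpha <- mean * (mean * (1 - mean) / sd^2 - 1)
  c(alpha = alpha, beta = alpha * (1 - mean) / mean)
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo resampling of the uncertain parameters: cost parameters from
#' gamma and probabilities/utilities from beta distributions matched to
#' each parameter's base value and standard error, the latter derived from
#' the +/-20% deterministic range treated as a 95% interval
#' (`sd = (high - low) / (2 * 1.96)`). Optionally (default), the survival
#' parameters of all four fits are drawn from the multivariate normal
#' implied by each fit's estimated covariance on the optimization scale.
#' The model is rerun per draw and the incremental cost/QALY pair recorded.
#'
#' @param ctx A [cea_context()].
#' @param n_draws Number of Monte-Carlo draws (default 5000).
#' @param seed Integer seed; fixed seed gives a bit-identical draw
#'   sequence.
#' @param vary_survival Sample survival-curve parameters too (default
#'   `TRUE`); set `FALSE` to freeze the fitted curves.
#' @param param_table Parameter table as from [dsa_default_ranges()];
#'   its `low`/`high` columns define the standard errors. A parameter with
#'   `high == low` is held fixed (point mass).
#' @return Object of class `psa_draws`: data.frame with columns `draw`,
#'   `delta_cost`, `delta_qaly`; attribute `base` holds the base-case
#'   [run_cea()] result.
#' @export
run_psa <- function(ctx, n_draws = 5000, seed = 42L, vary_survival = TRUE,
                    param_table = dsa_default_ranges(ctx$config)) {
  stopifnot(inherits(ctx, "cea_context"), n_draws >= 1)
  pt <- param_table
  pt$sd <- (pt$high - pt$low) / (2 * 1.96)
  # fail fast on infeasible distributions before any sampling
  for (r in seq_len(nrow(pt))) {
    if (pt$sd[r] <= 0) next
    if (pt$dist[r] == "gamma") moments_to_gamma(pt$base[r], pt$sd[r])
    else moments_to_beta(pt$base[r], pt$sd[r])
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draws_mat <- matrix(rep(pt$base, each = n_draws), nrow = n_draws,
                      dimnames = list(NULL, pt$id))
  for (r in seq_len(nrow(pt))) {
    if (pt$sd[r] <= 0) next
    draws_mat[, r] <- if (pt$dist[r] == "gamma") {
      g <- moments_to_gamma(pt$base[r], pt$sd[r])
      stats::rgamma(n_draws, shape = g["shape"], scale = g["scale"])
    } else {
      b <- moments_to_beta(pt$base[r], pt$sd[r])
      stats::rbeta(n_draws, b["alpha"], b["beta"])
    }
  }
  fit_draws <- NULL
  if (vary_survival) {
    fit_draws <- lapply(c(exp_os = "exp.os", exp_pfs = "exp.pfs",
                          ctl_os = "ctl.os", ctl_pfs = "ctl.pfs"),
                        function(key) {
      side <- if (startsWith(key, "exp")) ctx$exp_fits else ctx$ctl_fits
      fit <- side[[sub("^[a-z]+\\.", "", key)]]
      if (is.null(fit$covariance)) {
        matrix(rep(fit$opt_par, each = n_draws), nrow = n_draws)
      } else {
        sigma <- (fit$covariance + t(fit$covariance)) / 2
        MASS::mvrnorm(n_draws, mu = fit$opt_par, Sigma = sigma)
      }
    })
  }
  draw_fit <- function(fit, opt_row) {
    params <- exp(opt_row)
    if (fit$family == "lognormal") params[1] <- opt_row[1]
    names(params) <- names(fit$params)
    fit$params <- params
    fit
  }
  dc <- dq <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    cfg <- ctx$config
    for (r in seq_len(nrow(pt))) cfg <- set_param(cfg, pt$id[r], draws_mat[i, r])
    ef <- ctx$exp_fits; cf <- ctx$ctl_fits
    if (vary_survival) {
      ef$os <- draw_fit(ef$os, fit_draws$exp_os[i, ])
      ef$pfs <- draw_fit(ef$pfs, fit_draws$exp_pfs[i, ])
      cf$os <- draw_fit(cf$os, fit_draws$ctl_os[i, ])
      cf$pfs <- draw_fit(cf$pfs, fit_draws$ctl_pfs[i, ])
    }
    res <- run_cea(ef, cf, cfg, ctx$settings)
    dc[i] <- res$delta_cost
    dq[i] <- res$delta_qaly
  }
  out <- data.frame(draw = seq_len(n_draws), delta_cost = dc, delta_qaly = dq)
  attr(out, "base") <- context_run(ctx)
  class(out) <- c("psa_draws", "data.frame")
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with
#' positive net monetary benefit `wtp * delta_qaly - delta_cost > 0`.
#'
#' @param draws A [run_psa()] result (or data.frame with `delta_cost`,
#'   `delta_qaly`).
#' @param wtp_grid WTP values, USD/QALY; the default grid spans 0 to
#'   1.2e6 in 201 points, covering all four countries' thresholds and the
#'   reported CEAC turning points.
#' @return data.frame with columns `wtp`, `prob_ce`.
#' @export
ceac <- function(draws, wtp_grid = seq(0, 1.2e6, length.out = 201)) {
  stopifnot(nrow(draws) > 0)
  prob <- vapply(wtp_grid, function(l)
    mean(l * draws$delta_qaly - draws$delta_cost > 0), 0)
  data.frame(wtp = wtp_grid, prob_ce = prob)
}

#' Incremental cost-effectiveness plane quadrant counts
#'
#' Counts PSA draws per quadrant of the (delta QALY, delta cost) plane:
#' I more effective & costlier, II less effective & costlier, III less
#' effective & cheaper, IV more effective & cheaper. Boundary points
#' (a zero delta) are assigned to the positive side of that axis.
#'
#' @param draws A [run_psa()] result.
#' @return Named integer vector `c(I, II, III, IV)` summing to the number
#'   of draws.
#' @export
ice_quadrants <- function(draws) {
  stopifnot(nrow(draws) > 0)
  e_pos <- draws$delta_qaly >= 0
  c_pos <- draws$delta_cost >= 0
  c(I = sum(e_pos & c_pos), II = sum(!e_pos & c_pos),
    III = sum(!e_pos & !c_pos), IV = sum(e_pos & !c_pos))
}

# context with the pembrolizumab price scaled by (1 - reduction); the
# post-progression immunotherapy cycle is priced off the same vial, so it
# scales automatically
.reduce_pem_price <- function(ctx, reduction) {
  base_price <- ctx$config$drug_prices$pembrolizumab$price
  ctx$config$drug_prices$pembrolizumab$price <- base_price * (1 - reduction)
  ctx
}

#' Pembrolizumab price-reduction scenario grid
#'
#' Reruns the comparison with the pembrolizumab vial price scaled down by
#' each reduction (applied wherever pembrolizumab is costed: first line and
#' post-progression immunotherapy) and records the resulting ICER.
#'
#' @param ctx A [cea_context()].
#' @param reductions Price-reduction fractions (default the analysis grid
#'   10%-90% in steps of 10% plus 95%).
#' @return data.frame with columns `reduction`, `icer`, `delta_cost`,
#'   `delta_qaly`.
#' @export
scenario_price_grid <- function(ctx, reductions = c(seq(0.1, 0.9, by = 0.1), 0.95)) {
  stopifnot(inherits(ctx, "cea_context"),
            all(reductions >= 0 & reductions <= 1))
  rows <- lapply(reductions, function(r) {
    res <- context_run(.reduce_pem_price(ctx, r))
    data.frame(reduction = r, icer = res$icer, delta_cost = res$delta_cost,
               delta_qaly = res$delta_qaly)
  })
  do.call(rbind, rows)
}

#' Smallest pembrolizumab price reduction achieving cost-effectiveness
#'
#' Finds the smallest reduction fraction `r` with `ICER(r) <= wtp` by grid
#' bracketing followed by bisection to 0.1%. The ICER is monotone
#' decreasing in the reduction (only costs change), so the root is unique
#' when it exists.
#'
#' @param ctx A [cea_context()].
#' @param wtp Willingness-to-pay threshold (default the context config's).
#' @return List with `attainable` (logical) and `reduction` (fraction in
#'   `[0, 1]`, or `NA` when even a 100% price reduction leaves the ICER
#'   above `wtp`).
#' @export
price_threshold_for_wtp <- function(ctx, wtp = ctx$config$wtp) {
  stopifnot(inherits(ctx, "cea_context"), wtp > 0)
  icer_at <- function(r) context_run(.reduce_pem_price(ctx, r))$icer
  if (icer_at(0) <= wtp) return(list(attainable = TRUE, reduction = 0))
  if (icer_at(1) > wtp) return(list(attainable = FALSE, reduction = NA_real_))
  lo <- 0; hi <- 1
  grid <- seq(0.1, 0.9, by = 0.1)
  for (g in grid) {
    if (icer_at(g) > wtp) lo <- g else { hi <- g; break }
  }
  while (hi - lo > 0.001) {
    mid <- (lo + hi) / 2
    if (icer_at(mid) > wtp) lo <- mid else hi <- mid
  }
  list(attainable = TRUE, reduction = hi)
}
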