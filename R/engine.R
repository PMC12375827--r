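# Three-state partitioned survival engine: state occupancy from OS/PFS
# curves, regimen-aware cost accrual, QALY accrual, discounting, ICER.

#' State occupancy trajectory of the partitioned survival model
#'
#' Occupancy of the three states is read directly off the two survival
#' curves at each cycle's evaluation time: progression-free
#' `pi_pfs = min(S_pfs, S_os)` (clamped so PFS occupancy never exceeds
#' overall survival), dead `pi_death = 1 - S_os`, progressed
#' `pi_pd = S_os - pi_pfs`. Rows are cycles `i = 0 .. n_cycles - 1`
#' evaluated at cycle start `t_i = i * cycle_months` (the default), or at
#' cycle midpoints when `settings$half_cycle_correction` is set.
#'
#' @param os_fit,pfs_fit [fit_parametric()] objects for overall and
#'   progression-free survival of one arm.
#' @param settings A [model_settings()].
#' @return Object of class `state_trajectory`: data.frame with columns
#'   `cycle`, `eval_time` (months), `pi_pfs`, `pi_pd`, `pi_death`.
#' @export
build_trajectory <- function(os_fit, pfs_fit, settings = model_settings()) {
  n <- settings$n_cycles
  i <- seq_len(n) - 1L
  t_i <- (i + if (settings$half_cycle_correction) 0.5 else 0) * settings$cycle_months
  s_os <- survival_at(os_fit, t_i)
  s_pfs <- survival_at(pfs_fit, t_i)
  pi_pfs <- pmin(s_pfs, s_os)
  pi_death <- 1 - s_os
  pi_pd <- s_os - pi_pfs
  out <- data.frame(cycle = i, eval_time = t_i, pi_pfs = pi_pfs,
                    pi_pd = pi_pd, pi_death = pi_death)
  class(out) <- c("state_trajectory", "data.frame")
  out
}

# whole vials per administration; no vial sharing
.vials <- function(dose_mg, vial_mg) ceiling(dose_mg / vial_mg - 1e-9)

.drug_admin_cost <- function(drug, dose, per_bsa, config) {
  dp <- config$drug_prices[[drug]]
  if (is.null(dp)) stop("unknown drug in regimen: '", drug, "'", call. = FALSE)
  dose_mg <- if (per_bsa) dose * config$bsa else dose
  .vials(dose_mg, dp$vial_mg) * dp$price
}

#' First-line drug cost for one cycle
#'
#' Per fully-occupying patient and per cycle: for each regimen component,
#' the administered dose (flat mg, or mg/m^2 scaled by the configured BSA)
#' is rounded up to whole vials, priced at the per-vial price, and
#' multiplied by the administrations per cycle. A component contributes
#' nothing once `cycle_index` exceeds its maximum number of cycles
#' (pembrolizumab 35 cycles, cisplatin 8).
#'
#' @param arm `"experimental"` or `"control"`.
#' @param cycle_index Cycle number, 1-based.
#' @param config A [country_config()].
#' @return Undiscounted cost in USD.
#' @export
#' @examples
#' cfg <- builtin_configs()[["china"]]
#' drug_cost_cycle("experimental", 1, cfg)  # 5210.58
drug_cost_cycle <- function(arm, cycle_index, config) {
  stopifnot(cycle_index >= 1)
  reg <- regimen(arm)
  total <- 0
  for (r in seq_len(nrow(reg))) {
    if (cycle_index > reg$max_cycles[r]) next
    total <- total + .drug_admin_cost(reg$drug[r], reg$dose[r], reg$per_bsa[r],
                                      config) * reg$administrations_per_cycle[r]
  }
  total
}

# vector of first-line drug costs for cycles 1..n (fast path for accrual)
drug_cost_schedule <- function(arm, config, n_cycles) {
  reg <- regimen(arm)
  sched <- numeric(n_cycles)
  cyc <- seq_len(n_cycles)
  for (r in seq_len(nrow(reg))) {
    per_admin <- .drug_admin_cost(reg$drug[r], reg$dose[r], reg$per_bsa[r], config)
    sched <- sched + per_admin * reg$administrations_per_cycle[r] *
      (cyc <= reg$max_cycles[r])
  }
  sched
}

# cost of one 21-day cycle of second-line FOLFOX (prorated mFOLFOX6)
folfox_cycle_cost <- function(config) {
  fd <- config$folfox_doses
  sum(vapply(names(fd), function(d)
    .drug_admin_cost(d, fd[[d]], per_bsa = TRUE, config), 0))
}

# one pembrolizumab administration per cycle for post-progression IO
io_cycle_cost <- function(config) {
  .drug_admin_cost("pembrolizumab", config$io_dose_mg, per_bsa = FALSE, config)
}

#' Second-line cost per unit of progressed-state occupancy per cycle
#'
#' Progressed patients are a fixed mixture: a proportion on FOLFOX, a
#' proportion on post-progression immunotherapy (costed as one 200 mg
#' pembrolizumab administration per cycle), and the remainder on best
#' supportive care. The mixture weights are arm-specific trial proportions
#' (experimental 47% / 0.9%, control 49% / 1.1%).
#'
#' @param arm `"experimental"` or `"control"`.
#' @param config A [country_config()].
#' @return List with `total` plus components `folfox`, `io`, `bsc`
#'   (all USD per cycle per unit PD occupancy).
#' @export
second_line_cost_cycle <- function(arm, config) {
  arm <- match.arg(arm, c("experimental", "control"))
  p_fx <- if (arm == "experimental") config$second_line_prop_pem else config$second_line_prop_chem
  p_io <- if (arm == "experimental") config$io_prop_pem else config$io_prop_chem
  folfox <- p_fx * folfox_cycle_cost(config)
  io <- p_io * io_cycle_cost(config)
  bsc <- (1 - p_fx - p_io) * config$bsc_cost
  list(total = folfox + io + bsc, folfox = folfox, io = io, bsc = bsc)
}

#' Adverse-event management cost applied in the first cycle
#'
#' Sum over the four costed grade >=3 events (neutropenia, leukopenia,
#' thrombocytopenia, anemia) of the arm-specific probability times the
#' per-event management cost. The total is charged once, to the full
#' cohort, in the first treatment cycle only.
#'
#' @param arm `"experimental"` or `"control"`.
#' @param config A [country_config()].
#' @return One-off cost in USD.
#' @export
#' @examples
#' ae_cost_first_cycle("experimental", builtin_configs()[["china"]])  # 642.38
ae_cost_first_cycle <- function(arm, config) {
  arm <- match.arg(arm, c("experimental", "control"))
  probs <- unlist(if (arm == "experimental") config$ae_prob_pem else config$ae_prob_chem)
  costs <- unlist(config$ae_costs)
  sum(probs[AE_NAMES] * costs[AE_NAMES])
}

#' Discount factor at a given cycle
#'
#' `(1 + rate)^(-cycle_index * cycle_days / 365.25)`; cycle 0 (the model
#' start) is undiscounted.
#'
#' @param cycle_index 0-based cycle counter (vectorised).
#' @param rate Annual discount fraction, `>= 0`.
#' @param cycle_days Cycle length in days.
#' @return Factor in `(0, 1]`.
#' @export
discount_factor <- function(cycle_index, rate, cycle_days = 21) {
  stopifnot(rate >= 0)
  (1 + rate)^(-cycle_index * cycle_days / 365.25)
}

#' Accrue discounted costs and QALYs over a trajectory
#'
#' Per cycle row `i` (0-based, discounted by [discount_factor()] at `i`):
#' PFS occupants accrue first-line drug cost (cycle number `i + 1` for the
#' treatment caps) plus the administration cost; all alive patients accrue
#' the examination cost; PD occupants accrue the second-line mixture cost;
#' incremental deaths accrue the one-time end-of-life cost; the first row
#' additionally carries the cohort-level first-cycle AE cost. QALYs accrue
#' as `cycle_months / 12 * (u_pfs * pi_pfs + u_pd * pi_pd)` per row, and
#' the first row subtracts the configured AE disutility (0 in the base
#' case).
#'
#' @param traj A [build_trajectory()] result.
#' @param arm `"experimental"` or `"control"`.
#' @param config A [country_config()].
#' @param settings A [model_settings()].
#' @return Object of class `arm_result`: `total_cost`, `total_qaly`,
#'   `life_years` (discounted), and `breakdown` (named components:
#'   drug_first_line, drug_second_line, administration, examination, ae,
#'   bsc, eol).
#' @export
accrue <- function(traj, arm, config, settings = model_settings()) {
  stopifnot(inherits(traj, "state_trajectory"))
  arm <- match.arg(arm, c("experimental", "control"))
  n <- nrow(traj)
  df <- discount_factor(traj$cycle, config$discount_rate, settings$cycle_days)
  sched <- drug_cost_schedule(arm, config, n)  # by cycle number i+1
  sl <- second_line_cost_cycle(arm, config)
  new_deaths <- diff(c(0, traj$pi_death))
  first <- c(1, rep(0, n - 1L))

  comp <- c(
    drug_first_line = sum(traj$pi_pfs * sched * df),
    drug_second_line = sum(traj$pi_pd * (sl$folfox + sl$io) * df),
    administration = sum(traj$pi_pfs * config$administration_cost * df),
    examination = sum((traj$pi_pfs + traj$pi_pd) * config$examination_cost * df),
    ae = sum(first * ae_cost_first_cycle(arm, config) * df),
    bsc = sum(traj$pi_pd * sl$bsc * df),
    eol = sum(new_deaths * config$eol_cost * df)
  )
  cyc_yr <- settings$cycle_days / 365.25
  qaly <- sum(cyc_yr * (config$u_pfs * traj$pi_pfs + config$u_pd * traj$pi_pd) * df) -
    config$ae_disutility * df[1]
  ly <- sum(cyc_yr * (traj$pi_pfs + traj$pi_pd) * df)
  structure(list(total_cost = sum(comp), total_qaly = qaly,
                 life_years = ly, breakdown = comp, arm = arm),
            class = "arm_result")
}

#' Run the cost-effectiveness comparison of the two arms
#'
#' Builds both arms' trajectories from their OS/PFS fits, accrues
#' discounted costs and QALYs, and computes incremental cost, incremental
#' QALY and the ICER. When the signs disallow a meaningful ratio the
#' result carries a dominance status instead: `"dominant"` (cheaper and
#' more effective), `"dominated"` (costlier and less effective), or
#' `"undefined"` (no QALY difference); otherwise status is `"ICER"`.
#'
#' @param exp_fits,ctl_fits Lists with elements `os` and `pfs`
#'   ([fit_parametric()] objects) for the experimental and control arm.
#' @param config A [country_config()].
#' @param settings A [model_settings()].
#' @return Object of class `cea_result`: `experimental`, `control` (both
#'   [accrue()] results), `delta_cost`, `delta_qaly`, `icer` (numeric or
#'   `NA` when not meaningful), `status`, `country`, `wtp`.
#' @export
run_cea <- function(exp_fits, ctl_fits, config, settings = model_settings()) {
  stopifnot(all(c("os", "pfs") %in% names(exp_fits)),
            all(c("os", "pfs") %in% names(ctl_fits)))
  tr_exp <- build_trajectory(exp_fits$os, exp_fits$pfs, settings)
  tr_ctl <- build_trajectory(ctl_fits$os, ctl_fits$pfs, settings)
  res_exp <- accrue(tr_exp, "experimental", config, settings)
  res_ctl <- accrue(tr_ctl, "control", config, settings)
  dc <- res_exp$total_cost - res_ctl$total_cost
  dq <- res_exp$total_qaly - res_ctl$total_qaly
  if (abs(dq) < 1e-12) {
    status <- "undefined"; icer <- NA_real_
  } else if (dq > 0 && dc < 0) {
    status <- "dominant"; icer <- dc / dq
  } else if (dq < 0 && dc > 0) {
    status <- "dominated"; icer <- NA_real_
  } else {
    status <- "ICER"; icer <- dc / dq
  }
  structure(list(experimental = res_exp, control = res_ctl,
                 delta_cost = dc, delta_qaly = dq, icer = icer,
                 status = status, country = config$country,
                 wtp = config$wtp),
            class = "cea_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("<arm_result> %s: cost %s USD, %.4f QALY (%.4f LY), discounted\n",
              x$arm, format(round(x$total_cost, 2), big.mark = ","),
              x$total_qaly, x$life_years))
  invisible(x)
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result> ", x$country, "\n", sep = "")
  cat(sprintf("  experimental: cost %12s  QALY %.4f\n",
              format(round(x$experimental$total_cost, 2), big.mark = ","),
              x$experimental$total_qaly))
  cat(sprintf("  control     : cost %12s  QALY %.4f\n",
              format(round(x$control$total_cost, 2), big.mark = ","),
              x$control$total_qaly))
  cat(sprintf("  incremental : cost %12s  QALY %.4f\n",
              format(round(x$delta_cost, 2), big.mark = ","), x$delta_qaly))
  if (x$status == "ICER") {
    cat(sprintf("  ICER: %s USD/QALY (WTP %s)\n",
                format(round(x$icer, 2), big.mark = ","),
                format(x$wtp, big.mark = ",")))
  } else {
    cat("  status:", x$status, "\n")
  }
  invisible(x)
}
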