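cfg_china <- builtin_configs()[["china"]]

test_that("trajectory occupancy follows the partitioned-survival rule", {
  st <- model_settings()
  t1 <- st$cycle_months
  os <- make_fit("exponential", c(rate = -log(0.8) / t1))
  pfs <- make_fit("exponential", c(rate = -log(0.5) / t1))
  tr <- build_trajectory(os, pfs, st)
  expect_equal(unlist(tr[1, c("pi_pfs", "pi_pd", "pi_death")]),
               c(pi_pfs = 1, pi_pd = 0, pi_death = 0))  # cycle 0 at t = 0
  expect_equal(unlist(tr[2, c("pi_pfs", "pi_pd", "pi_death")]),
               c(pi_pfs = 0.5, pi_pd = 0.3, pi_death = 0.2))
  # PFS curve above OS is clamped to OS
  slow_pfs <- make_fit("exponential", c(rate = 1e-9))
  tr2 <- build_trajectory(os, slow_pfs, st)
  expect_equal(tr2$pi_pd, rep(0, st$n_cycles))
  expect_equal(tr2$pi_pfs, 1 - tr2$pi_death)
})

test_that("occupancy conserves mass to 1e-12 over all 174 cycles", {
  ctx <- make_context()
  for (fits in list(ctx$exp_fits, ctx$ctl_fits)) {
    tr <- build_trajectory(fits$os, fits$pfs, ctx$settings)
    expect_identical(nrow(tr), 174L)
    expect_lt(max(abs(tr$pi_pfs + tr$pi_pd + tr$pi_death - 1)), 1e-12)
    expect_true(all(diff(tr$pi_death) >= -1e-15))
    expect_true(all(diff(tr$pi_pfs) <= 1e-15))
    expect_true(all(tr$pi_pd >= -1e-15))
  }
})

test_that("half-cycle correction shifts evaluation to midpoints", {
  st <- model_settings(half_cycle_correction = TRUE)
  ctx <- make_context(settings = st)
  tr <- build_trajectory(ctx$exp_fits$os, ctx$exp_fits$pfs, st)
  expect_equal(tr$eval_time[1], 0.5 * st$cycle_months)
  expect_lt(tr$pi_pfs[1], 1)
})

test_that("first-line drug cost reproduces the vial-rounded hand arithmetic", {
  # China, experimental, cycle 1: pembrolizumab 2 vials x 2517.32;
  # gemcitabine ceil(1000*1.72/200) = 9 vials x 8.43 x 2 administrations;
  # cisplatin ceil(25*1.72/10) = 5 vials x 2.42 x 2
  expect_equal(drug_cost_cycle("experimental", 1, cfg_china),
               2 * 2517.32 + 9 * 8.43 * 2 + 5 * 2.42 * 2)
  expect_equal(drug_cost_cycle("experimental", 1, cfg_china), 5210.58)
  # cisplatin stops after cycle 8, pembrolizumab after cycle 35
  expect_equal(drug_cost_cycle("experimental", 9, cfg_china),
               5210.58 - 5 * 2.42 * 2)
  expect_equal(drug_cost_cycle("experimental", 36, cfg_china), 9 * 8.43 * 2)
  expect_equal(drug_cost_cycle("control", 1, cfg_china),
               9 * 8.43 * 2 + 5 * 2.42 * 2)
  expect_error(drug_cost_cycle("experimental", 0, cfg_china))
  # schedule vector agrees with the per-cycle function
  sched <- partsaCEA:::drug_cost_schedule("experimental", cfg_china, 40)
  expect_equal(sched, vapply(1:40, drug_cost_cycle, 0,
                             arm = "experimental", config = cfg_china))
  cfg_broken <- cfg_china
  cfg_broken$drug_prices$gemcitabine <- NULL
  expect_error(drug_cost_cycle("experimental", 1, cfg_broken), "unknown drug")
})

test_that("second-line mixture weights and linearity hold", {
  sl <- second_line_cost_cycle("experimental", cfg_china)
  fx <- partsaCEA:::folfox_cycle_cost(cfg_china)
  io <- partsaCEA:::io_cycle_cost(cfg_china)
  expect_equal(sl$folfox, 0.47 * fx)
  expect_equal(sl$io, 0.009 * io)
  expect_equal(sl$bsc, (1 - 0.47 - 0.009) * cfg_china$bsc_cost)
  expect_equal(sl$total, sl$folfox + sl$io + sl$bsc)
  ctl <- second_line_cost_cycle("control", cfg_china)
  expect_equal(ctl$folfox, 0.49 * fx)
  # degenerate mixture: no FOLFOX, no immunotherapy -> pure BSC
  cfg0 <- cfg_china
  cfg0$second_line_prop_pem <- 0; cfg0$io_prop_pem <- 0
  expect_equal(second_line_cost_cycle("experimental", cfg0)$total,
               cfg_china$bsc_cost)
  # doubling FOLFOX unit prices doubles the FOLFOX component only
  cfg2 <- cfg_china
  for (d in c("oxaliplatin", "leucovorin", "fluorouracil"))
    cfg2$drug_prices[[d]]$price <- 2 * cfg2$drug_prices[[d]]$price
  sl2 <- second_line_cost_cycle("experimental", cfg2)
  expect_equal(sl2$folfox, 2 * sl$folfox)
  expect_equal(sl2$io, sl$io)
  expect_equal(sl2$bsc, sl$bsc)
})

test_that("first-cycle AE cost matches hand arithmetic and is charged once", {
  expect_equal(ae_cost_first_cycle("experimental", cfg_china),
               0.47 * 354 + 0.12 * 466 + 0.16 * 1814 + 0.24 * 541)
  expect_equal(ae_cost_first_cycle("experimental", cfg_china), 642.38)
  cfg0 <- cfg_china
  for (ae in names(cfg0$ae_prob_pem)) cfg0$ae_prob_pem[[ae]] <- 0
  expect_equal(ae_cost_first_cycle("experimental", cfg0), 0)
  ctx <- make_context()
  tr <- build_trajectory(ctx$exp_fits$os, ctx$exp_fits$pfs, ctx$settings)
  res <- accrue(tr, "experimental", cfg_china, ctx$settings)
  expect_equal(unname(res$breakdown["ae"]),
               ae_cost_first_cycle("experimental", cfg_china))
})

test_that("discount factors follow (1+r)^(-t years)", {
  expect_equal(discount_factor(0:10, 0), rep(1, 11))
  expect_equal(discount_factor(0, 0.07), 1)
  expect_equal(discount_factor(365.25 / 21, 0.05), 1 / 1.05)
  expect_error(discount_factor(1, -0.1))
})

test_that("accrual identities: utility-1 life-years, single-cycle QALY, eol", {
  ctx <- make_context()
  cfg <- cfg_china
  cfg$discount_rate <- 0
  cfg$u_pfs <- 1; cfg$u_pd <- 1
  tr <- build_trajectory(ctx$exp_fits$os, ctx$exp_fits$pfs, ctx$settings)
  res <- accrue(tr, "experimental", cfg, ctx$settings)
  expect_equal(res$total_qaly, 21 / 365.25 * sum(tr$pi_pfs + tr$pi_pd))
  expect_equal(res$total_qaly, res$life_years)
  # one cycle fully in PFS at u = 0.76, undiscounted
  one <- structure(data.frame(cycle = 0L, eval_time = 0, pi_pfs = 1,
                              pi_pd = 0, pi_death = 0),
                   class = c("state_trajectory", "data.frame"))
  cfg2 <- cfg_china; cfg2$discount_rate <- 0
  expect_equal(accrue(one, "experimental", cfg2, ctx$settings)$total_qaly,
               0.76 * 21 / 365.25, tolerance = 1e-6)
  # telescoping: undiscounted end-of-life cost = eol_cost * final deaths
  res2 <- accrue(tr, "experimental", cfg2, ctx$settings)
  expect_equal(unname(res2$breakdown["eol"]),
               cfg2$eol_cost * tr$pi_death[nrow(tr)])
})

test_that("degenerate configs zero out the matching accrual components", {
  ctx <- make_context()
  tr <- build_trajectory(ctx$exp_fits$os, ctx$exp_fits$pfs, ctx$settings)
  zero_price <- cfg_china
  for (d in names(zero_price$drug_prices)) zero_price$drug_prices[[d]]$price <- 0
  res <- accrue(tr, "experimental", zero_price, ctx$settings)
  expect_equal(unname(res$breakdown["drug_first_line"]), 0)
  expect_equal(unname(res$breakdown["drug_second_line"]), 0)
  expect_gt(res$total_cost, 0)  # per-cycle and AE components remain
  zero_u <- cfg_china; zero_u$u_pfs <- 0; zero_u$u_pd <- 0
  expect_equal(accrue(tr, "experimental", zero_u, ctx$settings)$total_qaly, 0)
  all_zero <- zero_price
  all_zero$u_pfs <- 0; all_zero$u_pd <- 0
  for (f in c("examination_cost", "administration_cost", "bsc_cost", "eol_cost"))
    all_zero[[f]] <- 0
  for (ae in AE_NAMES) all_zero$ae_costs[[ae]] <- 0
  res0 <- accrue(tr, "experimental", all_zero, ctx$settings)
  expect_equal(res0$total_cost, 0)
  expect_equal(res0$total_qaly, 0)
})

test_that("total cost always equals the sum of its breakdown", {
  ctx <- make_context()
  for (arm in c("experimental", "control")) {
    fits <- if (arm == "experimental") ctx$exp_fits else ctx$ctl_fits
    tr <- build_trajectory(fits$os, fits$pfs, ctx$settings)
    res <- accrue(tr, arm, cfg_china, ctx$settings)
    expect_equal(res$total_cost, sum(res$breakdown))
    expect_true(all(res$breakdown >= 0))
  }
})

test_that("zero-rate discounting reproduces an independent undiscounted loop", {
  ctx <- make_context()
  cfg <- cfg_china; cfg$discount_rate <- 0
  st <- ctx$settings
  res <- accrue(build_trajectory(ctx$exp_fits$os, ctx$exp_fits$pfs, st),
                "experimental", cfg, st)
  # independent oracle: naive per-cycle loop, no vectorization, no discount
  sl <- second_line_cost_cycle("experimental", cfg)
  total <- 0; qaly <- 0; prev_death <- 0
  for (i in 0:(st$n_cycles - 1)) {
    t_i <- i * st$cycle_months
    s_os <- exp(-log(2) / 12.7 * t_i); s_pfs <- exp(-log(2) / 6.5 * t_i)
    p_pfs <- min(s_pfs, s_os); p_death <- 1 - s_os; p_pd <- s_os - p_pfs
    total <- total + p_pfs * (drug_cost_cycle("experimental", i + 1, cfg) +
                                cfg$administration_cost) +
      (p_pfs + p_pd) * cfg$examination_cost + p_pd * sl$total +
      (p_death - prev_death) * cfg$eol_cost +
      (if (i == 0) ae_cost_first_cycle("experimental", cfg) else 0)
    qaly <- qaly + 21 / 365.25 * (cfg$u_pfs * p_pfs + cfg$u_pd * p_pd)
    prev_death <- p_death
  }
  expect_equal(res$total_cost, total, tolerance = 1e-10)
  expect_equal(res$total_qaly, qaly, tolerance = 1e-10)
})

test_that("ICER and dominance statuses follow the sign conventions", {
  ctx <- make_context()
  res <- context_run(ctx)
  expect_identical(res$status, "ICER")
  expect_equal(res$icer, res$delta_cost / res$delta_qaly)
  expect_equal(res$delta_cost,
               res$experimental$total_cost - res$control$total_cost)
  expect_equal(res$delta_qaly,
               res$experimental$total_qaly - res$control$total_qaly)
  # identical survival in both arms: no QALY difference -> undefined
  same <- run_cea(ctx$ctl_fits, ctx$ctl_fits, cfg_china, ctx$settings)
  expect_identical(same$status, "undefined")
  expect_true(is.na(same$icer))
  # control arm survives longer while the experimental regimen costs more
  flipped <- run_cea(ctx$ctl_fits, ctx$exp_fits, cfg_china, ctx$settings)
  expect_identical(flipped$status, "dominated")
  expect_true(is.na(flipped$icer))
  # better survival and lower cost: only end-of-life cost differs
  cfg_eol <- cfg_china
  for (d in names(cfg_eol$drug_prices)) cfg_eol$drug_prices[[d]]$price <- 0
  for (f in c("examination_cost", "administration_cost", "bsc_cost"))
    cfg_eol[[f]] <- 0
  for (ae in AE_NAMES) cfg_eol$ae_costs[[ae]] <- 0
  dom <- run_cea(ctx$exp_fits, ctx$ctl_fits, cfg_eol, ctx$settings)
  expect_identical(dom$status, "dominant")
})

test_that("ICER is monotone increasing in the pembrolizumab vial price", {
  ctx <- make_context()
  icers <- vapply(c(0.5, 1, 2), function(mult) {
    cfg <- cfg_china
    cfg$drug_prices$pembrolizumab$price <-
      cfg$drug_prices$pembrolizumab$price * mult
    run_cea(ctx$exp_fits, ctx$ctl_fits, cfg, ctx$settings)$icer
  }, 0)
  expect_true(all(diff(icers) > 0))
})
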