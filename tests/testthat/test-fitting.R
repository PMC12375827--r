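test_that("exponential MLE matches the closed form events / total time", {
  fit <- fit_parametric(pseudo_ipd(c(1, 2, 3), c(1, 1, 1)), "exponential")
  expect_equal(unname(fit$params["rate"]), 0.5, tolerance = 1e-8)
  # with censoring
  ipd <- pseudo_ipd(c(1, 2, 3, 4), c(1, 0, 1, 0))
  fit2 <- fit_parametric(ipd, "exponential")
  expect_equal(unname(fit2$params["rate"]), 2 / 10, tolerance = 1e-8)
  expect_error(fit_parametric(pseudo_ipd(c(1, 2), c(0, 0)), "exponential"),
               "zero events")
})

test_that("information criteria follow their formulas", {
  fit <- fit_parametric(pseudo_ipd(c(1, 2, 3), c(1, 1, 1)), "weibull")
  expect_equal(fit$aic, 2 * 2 - 2 * fit$loglik)
  expect_equal(fit$bic, 2 * log(3) - 2 * fit$loglik)
  # formula substitution: k = 2, loglik = -50, n = 100
  expect_equal(2 * 2 - 2 * (-50), 104)
  expect_equal(2 * log(100) - 2 * (-50), 109.2103, tolerance = 1e-4)
})

test_that("weibull parameters are recovered within 5% at n = 2000", {
  t <- sample_times("weibull", c(shape = 1.5, scale = 10), 2000, seed = 5)
  fit <- fit_parametric(pseudo_ipd(t, rep(1, 2000)), "weibull")
  expect_lt(abs(fit$params["shape"] - 1.5) / 1.5, 0.05)
  expect_lt(abs(fit$params["scale"] - 10) / 10, 0.05)
})

test_that("each family's likelihood agrees with flexsurv on censored data", {
  arm <- generate_arm(arm_spec(300, 6.5, 12.7, seed = 17))
  map <- c(exponential = "exp", weibull = "weibull", gamma = "gamma",
           loglogistic = "llogis", lognormal = "lnorm")
  for (fam in names(map)) {
    fit <- fit_parametric(arm$os, fam)
    ref <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1,
                                 data = as.data.frame(arm$os),
                                 dist = map[[fam]])
    expect_equal(fit$loglik, ref$loglik, tolerance = 1e-4, label = fam)
  }
})

test_that("implemented densities match the numeric derivative of survival", {
  set.seed(99)
  params <- list(exponential = c(rate = 0.08),
                 weibull = c(shape = 1.4, scale = 11),
                 gamma = c(shape = 2.2, rate = 0.2),
                 loglogistic = c(scale = 9, shape = 2.5),
                 lognormal = c(meanlog = 2.1, sdlog = 0.6))
  h <- 1e-6
  for (fam in names(params)) {
    t <- runif(200, 0.5, 40)
    f <- surv_density(fam, params[[fam]], t)
    df <- -(surv_survival(fam, params[[fam]], t + h) -
              surv_survival(fam, params[[fam]], t - h)) / (2 * h)
    expect_lt(max(abs(f - df) / pmax(f, 1e-12)), 1e-5, label = fam)
  }
})

test_that("a near-zero pure-censoring observation leaves the MLE unchanged", {
  t <- sample_times("weibull", c(shape = 1.3, scale = 9), 400, seed = 23)
  base <- fit_parametric(pseudo_ipd(t, rep(1, 400)), "weibull")
  aug <- fit_parametric(pseudo_ipd(c(t, 1e-9), c(rep(1, 400), 0)), "weibull")
  expect_equal(base$params, aug$params, tolerance = 1e-5)
})

test_that("exponential rate estimate is nearly unbiased at n = 5000", {
  rates <- vapply(1:20, function(s) {
    t <- sample_times("exponential", c(rate = 0.1), 5000, seed = s)
    fit_parametric(pseudo_ipd(t, rep(1, 5000)), "exponential")$params["rate"]
  }, 0)
  expect_lt(abs(mean(rates) - 0.1) / 0.1, 0.02)
})

test_that("selection minimizes the criterion with documented tie-breaks", {
  arm <- generate_arm(arm_spec(200, 6.5, 12.7, seed = 2))
  fits <- fit_all_families(arm$os)
  sel <- select_distribution(fits, "AIC")
  expect_equal(sel$aic, min(vapply(fits, `[[`, 0, "aic")))
  selb <- select_distribution(fits, "BIC")
  expect_equal(selb$bic, min(vapply(fits, `[[`, 0, "bic")))
  # single candidate
  expect_identical(select_distribution(fits["gamma"], "AIC")$family, "gamma")
  # equal criterion: fewer parameters wins, then fixed family order
  f1 <- make_fit("weibull", c(shape = 1, scale = 10), loglik = -49)
  f2 <- make_fit("exponential", c(rate = 0.1), loglik = -50)
  expect_identical(select_distribution(list(f1, f2), "AIC")$family,
                   "exponential")
  f3 <- make_fit("lognormal", c(meanlog = 2, sdlog = 1), loglik = -49)
  expect_identical(select_distribution(list(f3, f1), "AIC")$family, "weibull")
  # mixed samples rejected
  f4 <- make_fit("gamma", c(shape = 1, rate = 1), n_obs = 50)
  expect_error(select_distribution(list(f1, f4)), "mixed n_obs")
})

test_that("survival evaluation follows the closed forms", {
  for (fam in SURV_FAMILIES) {
    p <- switch(fam, exponential = c(rate = 0.1),
                weibull = c(shape = 1.5, scale = 10),
                gamma = c(shape = 2, rate = 0.2),
                loglogistic = c(scale = 8, shape = 2),
                lognormal = c(meanlog = 2, sdlog = 0.5))
    fit <- make_fit(fam, p)
    expect_equal(unname(survival_at(fit, 0)), 1, label = fam)
    expect_error(survival_at(fit, -1), "t < 0")
  }
  exp_fit_ <- make_fit("exponential", c(rate = log(2) / 12.7))
  expect_equal(unname(survival_at(exp_fit_, 12.7)), 0.5)
  w1 <- make_fit("weibull", c(shape = 1, scale = 10))
  e1 <- make_fit("exponential", c(rate = 1 / 10))
  expect_equal(survival_at(w1, 3.7), survival_at(e1, 3.7), tolerance = 1e-12)
})

test_that("fitted medians match closed forms and a bisection oracle", {
  expect_equal(median_of_fit(make_fit("exponential", c(rate = 0.2))),
               log(2) / 0.2)
  expect_equal(median_of_fit(make_fit("lognormal", c(meanlog = 2, sdlog = 0.7))),
               exp(2))
  expect_equal(median_of_fit(make_fit("loglogistic", c(scale = 7, shape = 2))), 7)
  wb <- make_fit("weibull", c(shape = 1.5, scale = 10))
  expect_equal(unname(survival_at(wb, median_of_fit(wb))), 0.5, tolerance = 1e-10)
  # gamma: bracketed bisection on S(t) = 0.5 as the independent oracle
  gm <- make_fit("gamma", c(shape = 2.3, rate = 0.21))
  lo <- 1e-8; hi <- 1000
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (survival_at(gm, mid) > 0.5) lo <- mid else hi <- mid
  }
  expect_equal(median_of_fit(gm), (lo + hi) / 2, tolerance = 1e-6)
})

test_that("fit summary flags exactly the selected family", {
  arm <- generate_arm(arm_spec(150, 6.5, 12.7, seed = 4))
  fits <- fit_all_families(arm$pfs)
  tab <- fit_summary(fits, "AIC")
  expect_identical(nrow(tab), 5L)
  expect_identical(sum(tab$selected), 1L)
  expect_identical(tab$family[tab$selected],
                   select_distribution(fits, "AIC")$family)
})
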