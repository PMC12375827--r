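#' @importFrom stats optim uniroot qexp qweibull qgamma qlnorm rgamma rbeta
#'   runif setNames pexp pweibull pgamma plnorm dlnorm dgamma dweibull dexp
#'   quantile rnorm
#' @importFrom utils read.csv write.csv modifyList
NULL

# Names of the four grade >=3 adverse events costed in the first cycle.
AE_NAMES <- c("neutropenia", "leukopenia", "thrombocytopenia", "anemia")

# Drugs the model can price. FOLFOX components are needed even for the
# first-line regimens because second-line therapy is costed in both arms.
DRUG_NAMES <- c("pembrolizumab", "gemcitabine", "cisplatin",
                "fluorouracil", "leucovorin", "oxaliplatin")

.config_required_fields <- c(
  "country", "drug_prices", "ae_costs", "ae_prob_pem", "ae_prob_chem",
  "examination_cost", "administration_cost", "bsc_cost", "eol_cost",
  "u_pfs", "u_pd", "bsa", "discount_rate", "wtp"
)

.config_optional_fields <- c(
  "second_line_prop_pem", "second_line_prop_chem",
  "io_prop_pem", "io_prop_chem", "folfox_doses", "io_dose_mg",
  "exchange_rate_note", "ae_disutility"
)

#' Construct a validated country configuration
#'
#' A `country_config` bundles every country-specific economic input of the
#' model: per-vial drug prices, adverse-event (AE) management costs and
#' per-arm AE probabilities, per-cycle examination / administration / best
#' supportive care costs, one-time end-of-life cost, health-state utilities,
#' body surface area (BSA), annual discount rate and the willingness-to-pay
#' (WTP) threshold. Proportions of progressed patients receiving second-line
#' FOLFOX and post-progression immunotherapy default to the trial-reported
#' values (47%/0.9% in the pembrolizumab arm, 49%/1.1% in the chemotherapy
#' arm); the remainder receives best supportive care.
#'
#' @param country Country identifier (character scalar).
#' @param drug_prices Named list; one entry per drug in
#'   `c("pembrolizumab","gemcitabine","cisplatin","fluorouracil","leucovorin","oxaliplatin")`,
#'   each a list with `vial_mg` (vial size, mg) and `price` (USD per vial).
#'   Vial sizes are explicit per country: e.g. cisplatin is priced per 50 mg
#'   vial in Japan but per 10 mg vial elsewhere.
#' @param ae_costs Named numeric; one-off management cost (USD) for each of
#'   neutropenia, leukopenia, thrombocytopenia, anemia.
#' @param ae_prob_pem,ae_prob_chem Named numeric; per-arm probabilities of
#'   the same four events.
#' @param examination_cost,administration_cost,bsc_cost Numeric, USD per
#'   21-day cycle.
#' @param eol_cost Numeric, one-time end-of-life cost (USD) applied to each
#'   incremental death.
#' @param u_pfs,u_pd Utilities of the progression-free and progressed states,
#'   in `[0, 1]` with `u_pd <= u_pfs`.
#' @param bsa Mean body surface area in m^2 (scales mg/m^2 doses).
#' @param discount_rate Annual discount fraction for costs and QALYs.
#' @param wtp Willingness-to-pay threshold, USD per QALY.
#' @param second_line_prop_pem,second_line_prop_chem Proportion of progressed
#'   patients receiving FOLFOX, per arm.
#' @param io_prop_pem,io_prop_chem Proportion of progressed patients
#'   receiving post-progression immunotherapy, per arm.
#' @param folfox_doses Optional named numeric overriding the per-cycle FOLFOX
#'   doses in mg/m^2 (names `oxaliplatin`, `leucovorin`, `fluorouracil`).
#'   Defaults to mFOLFOX6 prorated from a 14-day to a 21-day cycle
#'   (127.5 / 600 / 4200 mg/m^2).
#' @param io_dose_mg Flat pembrolizumab dose (mg) used to price one cycle of
#'   post-progression immunotherapy; default 200.
#' @param ae_disutility One-off utility decrement applied in the first cycle
#'   (AE disutility); default 0 (base case omits it).
#' @param exchange_rate_note Free-text metadata (never used in computation).
#'
#' @return An object of class `country_config` (a named list).
#' @export
#' @examples
#' cfg <- builtin_configs()[["china"]]
#' cfg$wtp
country_config <- function(country, drug_prices, ae_costs,
                           ae_prob_pem, ae_prob_chem,
                           examination_cost, administration_cost,
                           bsc_cost, eol_cost,
                           u_pfs, u_pd, bsa, discount_rate, wtp,
                           second_line_prop_pem = 0.47,
                           second_line_prop_chem = 0.49,
                           io_prop_pem = 0.009,
                           io_prop_chem = 0.011,
                           folfox_doses = NULL,
                           io_dose_mg = 200,
                           ae_disutility = 0,
                           exchange_rate_note = NULL) {
  cfg <- list(
    country = country,
    drug_prices = drug_prices,
    ae_costs = ae_costs,
    ae_prob_pem = ae_prob_pem,
    ae_prob_chem = ae_prob_chem,
    examination_cost = examination_cost,
    administration_cost = administration_cost,
    bsc_cost = bsc_cost,
    eol_cost = eol_cost,
    u_pfs = u_pfs,
    u_pd = u_pd,
    bsa = bsa,
    discount_rate = discount_rate,
    wtp = wtp,
    second_line_prop_pem = second_line_prop_pem,
    second_line_prop_chem = second_line_prop_chem,
    io_prop_pem = io_prop_pem,
    io_prop_chem = io_prop_chem,
    folfox_doses = folfox_doses %||%
      c(oxaliplatin = 127.5, leucovorin = 600, fluorouracil = 4200),
    io_dose_mg = io_dose_mg,
    ae_disutility = ae_disutility,
    exchange_rate_note = exchange_rate_note
  )
  class(cfg) <- "country_config"
  validate_country_config(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.cfg_stop <- function(...) stop("config validation: ", ..., call. = FALSE)

#' Validate a country configuration
#'
#' Checks every invariant of the configuration contract and fails with an
#' error naming the offending field or constraint.
#'
#' @param cfg A `country_config`.
#' @return `cfg`, invisibly unchanged, if valid.
#' @export
validate_country_config <- function(cfg) {
  for (f in .config_required_fields) {
    if (is.null(cfg[[f]])) .cfg_stop("missing required field '", f, "'")
  }
  num1 <- function(x, f) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      .cfg_stop("field '", f, "' must be a finite numeric scalar")
  }
  dp <- cfg$drug_prices
  missing_drugs <- setdiff(DRUG_NAMES, names(dp))
  if (length(missing_drugs))
    .cfg_stop("missing drug price for '", missing_drugs[1L], "'")
  for (d in names(dp)) {
    if (!d %in% DRUG_NAMES) .cfg_stop("unknown drug '", d, "' in drug_prices")
    num1(dp[[d]]$vial_mg, paste0("drug_prices.", d, ".vial_mg"))
    num1(dp[[d]]$price, paste0("drug_prices.", d, ".price"))
    if (dp[[d]]$vial_mg <= 0) .cfg_stop("vial_mg must be > 0 for '", d, "'")
    if (dp[[d]]$price < 0) .cfg_stop("price must be >= 0 for '", d, "'")
  }
  for (slot in c("ae_costs", "ae_prob_pem", "ae_prob_chem")) {
    v <- unlist(cfg[[slot]])
    missing_ae <- setdiff(AE_NAMES, names(v))
    if (length(missing_ae))
      .cfg_stop("missing AE entry '", missing_ae[1L], "' in ", slot)
    extra <- setdiff(names(v), AE_NAMES)
    if (length(extra)) .cfg_stop("unknown AE '", extra[1L], "' in ", slot)
    if (any(v < 0)) .cfg_stop("negative value in ", slot)
  }
  if (any(unlist(cfg$ae_prob_pem) > 1) || any(unlist(cfg$ae_prob_chem) > 1))
    .cfg_stop("AE probability outside [0,1]")
  for (f in c("examination_cost", "administration_cost", "bsc_cost",
              "eol_cost", "u_pfs", "u_pd", "bsa", "discount_rate", "wtp",
              "second_line_prop_pem", "second_line_prop_chem",
              "io_prop_pem", "io_prop_chem", "io_dose_mg", "ae_disutility")) {
    num1(cfg[[f]], f)
  }
  if (cfg$u_pfs < 0 || cfg$u_pfs > 1 || cfg$u_pd < 0 || cfg$u_pd > 1)
    .cfg_stop("utility outside [0,1]")
  if (cfg$u_pd > cfg$u_pfs) .cfg_stop("u_pd must not exceed u_pfs")
  for (f in c("second_line_prop_pem", "second_line_prop_chem",
              "io_prop_pem", "io_prop_chem")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) .cfg_stop("proportion '", f, "' outside [0,1]")
  }
  if (cfg$second_line_prop_pem + cfg$io_prop_pem > 1)
    .cfg_stop("second-line + immunotherapy proportions exceed 1 (pem arm)")
  if (cfg$second_line_prop_chem + cfg$io_prop_chem > 1)
    .cfg_stop("second-line + immunotherapy proportions exceed 1 (chem arm)")
  if (cfg$discount_rate < 0) .cfg_stop("discount_rate must be >= 0")
  if (cfg$wtp <= 0) .cfg_stop("wtp must be > 0")
  if (cfg$bsa <= 0) .cfg_stop("bsa must be > 0")
  fd <- cfg$folfox_doses
  if (!all(c("oxaliplatin", "leucovorin", "fluorouracil") %in% names(fd)) ||
      any(fd <= 0))
    .cfg_stop("folfox_doses must name positive oxaliplatin/leucovorin/fluorouracil doses")
  invisible(cfg)
}

#' Load a country configuration from a YAML file
#'
#' Reads one country's model inputs from the documented YAML schema (see the
#' files under `system.file("extdata", package = "partsaCEA")` for the four
#' shipped examples). Unknown keys are rejected so typos cannot silently
#' fall back to defaults.
#'
#' @param path Path to a YAML config file.
#' @return A validated [country_config()].
#' @export
#' @examples
#' path <- system.file("extdata", "china.yaml", package = "partsaCEA")
#' cfg <- load_country_config(path)
#' cfg$u_pfs  # 0.76
load_country_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- c(.config_required_fields, .config_optional_fields)
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    .cfg_stop("unknown key '", unknown[1L], "' in ", path)
  missing <- setdiff(.config_required_fields, names(raw))
  if (length(missing))
    .cfg_stop("missing required field '", missing[1L], "' in ", path)
  if (!is.null(raw$folfox_doses)) raw$folfox_doses <- unlist(raw$folfox_doses)
  do.call(country_config, raw)
}

#' Write a country configuration to a YAML file
#'
#' Inverse of [load_country_config()]: `load_country_config(write_country_config(cfg, f))`
#' reproduces `cfg` on all fields.
#'
#' @param cfg A `country_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_country_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "country_config"))
  out <- unclass(cfg)
  out$folfox_doses <- as.list(out$folfox_doses)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Built-in country configurations
#'
#' Returns the four configurations shipped with the package (China, Japan,
#' United States, Switzerland), loaded from the packaged YAML files. Every
#' numeric field carries the published model-input value for that country;
#' all prices are USD (the exchange rates used by the sources are recorded
#' as metadata only and never applied in computation).
#'
#' @return Named list of [country_config()] objects with names
#'   `"china"`, `"japan"`, `"us"`, `"switzerland"`.
#' @export
#' @examples
#' builtin_configs()[["japan"]]$bsa  # 1.73
builtin_configs <- function() {
  countries <- c("china", "japan", "us", "switzerland")
  cfgs <- lapply(countries, function(cc) {
    load_country_config(system.file("extdata", paste0(cc, ".yaml"),
                                    package = "partsaCEA", mustWork = TRUE))
  })
  stats::setNames(cfgs, countries)
}

#' @export
print.country_config <- function(x, ...) {
  cat("<country_config> ", x$country, "\n", sep = "")
  cat(sprintf("  WTP threshold : %s USD/QALY\n", format(x$wtp, big.mark = ",")))
  cat(sprintf("  discount rate : %.2f / year\n", x$discount_rate))
  cat(sprintf("  utilities     : PFS %.2f, PD %.2f\n", x$u_pfs, x$u_pd))
  cat(sprintf("  BSA           : %.2f m^2\n", x$bsa))
  cat(sprintf("  drugs priced  : %s\n", paste(names(x$drug_prices), collapse = ", ")))
  invisible(x)
}

#' Model settings
#'
#' Global settings of the partitioned survival model: a 21-day cycle over a
#' 10-year horizon, giving `ceiling(10 * 365.25 / 21) = 174` cycles so the
#' final partial year is covered rather than truncated. State occupancy is
#' evaluated at cycle start by default; `half_cycle_correction = TRUE`
#' switches the evaluation to cycle midpoints.
#'
#' @param cycle_days Cycle length in days (default 21).
#' @param horizon_years Model horizon in years (default 10).
#' @param half_cycle_correction Evaluate occupancy at cycle midpoints
#'   instead of cycle starts (default `FALSE`).
#' @param seed Integer seed recorded for downstream stochastic stages.
#' @return An object of class `model_settings` with derived `n_cycles` and
#'   `cycle_months` (cycle length in months, `cycle_days / 365.25 * 12`).
#' @export
#' @examples
#' model_settings()$n_cycles  # 174
model_settings <- function(cycle_days = 21, horizon_years = 10,
                           half_cycle_correction = FALSE, seed = 42L) {
  stopifnot(cycle_days > 0, horizon_years > 0)
  s <- list(
    cycle_days = cycle_days,
    horizon_years = horizon_years,
    n_cycles = as.integer(ceiling(horizon_years * 365.25 / cycle_days)),
    cycle_months = cycle_days / 365.25 * 12,
    half_cycle_correction = isTRUE(half_cycle_correction),
    seed = as.integer(seed)
  )
  class(s) <- "model_settings"
  s
}

#' First-line treatment regimens
#'
#' Returns the regimen costed for PFS-state occupants of one arm, as a data
#' frame of components. Doses follow the trial protocol: the experimental
#' arm receives pembrolizumab 200 mg flat once per cycle for at most 35
#' cycles plus gemcitabine 1,000 mg/m^2 and cisplatin 25 mg/m^2 on days 1
#' and 8 of each 21-day cycle, cisplatin capped at 8 cycles; the control arm
#' receives the chemotherapy backbone only. Gemcitabine (and pembrolizumab
#' within its cap) is given until progression.
#'
#' @param arm `"experimental"` (pembrolizumab + gemcitabine/cisplatin) or
#'   `"control"` (gemcitabine/cisplatin).
#' @return data.frame with columns `drug`, `dose` (mg or mg/m^2),
#'   `per_bsa` (logical; `TRUE` means the dose is mg/m^2),
#'   `administrations_per_cycle`, `max_cycles` (`Inf` when uncapped).
#' @export
regimen <- function(arm = c("experimental", "control")) {
  arm <- match.arg(arm)
  chemo <- data.frame(
    drug = c("gemcitabine", "cisplatin"),
    dose = c(1000, 25),
    per_bsa = c(TRUE, TRUE),
    administrations_per_cycle = c(2L, 2L),
    max_cycles = c(Inf, 8),
    stringsAsFactors = FALSE
  )
  if (arm == "control") return(chemo)
  rbind(
    data.frame(drug = "pembrolizumab", dose = 200, per_bsa = FALSE,
               administrations_per_cycle = 1L, max_cycles = 35,
               stringsAsFactors = FALSE),
    chemo
  )
}
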