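# Model parameters: single source of truth for transition probabilities,
# relative risks, costs, utilities, discounting and sensitivity-analysis
# specifications. Values shipped here are plausible placeholders for a
# Chinese payer-perspective analysis (2017 Int$), clearly replaceable via
# YAML/JSON configuration; they are NOT the original study's supplementary
# table values, which are not in the public text.

#' Sex-specific Framingham general cardiovascular risk coefficients
#'
#' Published Cox-model coefficients of the Framingham 10-year general
#' cardiovascular disease risk function for use in primary care
#' (log-transformed continuous covariates; separate systolic blood pressure
#' coefficients for treated and untreated individuals). `s0` is the 10-year
#' baseline survival and `mean_lp` the linear predictor evaluated at the
#' derivation-cohort covariate means.
#'
#' @return Named list with elements `male` and `female`, each a list of
#'   coefficients: `ln_age`, `ln_tc`, `ln_hdl`, `ln_sbp_untreated`,
#'   `ln_sbp_treated`, `smoker`, `diabetes`, `s0`, `mean_lp`.
#' @export
framingham_gcvd_coefficients <- function() {
  list(
    male = list(
      ln_age = 3.06117, ln_tc = 1.12370, ln_hdl = -0.93263,
      ln_sbp_untreated = 1.93303, ln_sbp_treated = 1.99881,
      smoker = 0.65451, diabetes = 0.57367,
      s0 = 0.88936, mean_lp = 23.9802
    ),
    female = list(
      ln_age = 2.32888, ln_tc = 1.20904, ln_hdl = -0.70833,
      ln_sbp_untreated = 2.76157, ln_sbp_treated = 2.82263,
      smoker = 0.52873, diabetes = 0.69154,
      s0 = 0.95012, mean_lp = 26.1931
    )
  )
}

#' Default synthetic life table
#'
#' Annual all-cause death probabilities by single year of age and sex from a
#' Gompertz hazard `mu(age) = a * exp(b * age)`, with constants calibrated so
#' that whole-year remaining life expectancy at age 45 is about 31 years for
#' men and 36 years for women (similar to Chinese period life tables around
#' 2017). This is a synthetic stand-in: real analyses should supply a
#' national life table via [read_life_table()].
#'
#' @param ages Integer vector of ages covered (default 0 to 109).
#' @return `data.frame` with columns `age`, `sex`, `qx` (annual probability
#'   of death).
#' @export
default_life_table <- function(ages = 0:109) {
  gomp <- function(a, b) 1 - exp(-a * exp(b * ages))
  rbind(
    data.frame(age = ages, sex = "male",   qx = gomp(4.92e-05, 0.095)),
    data.frame(age = ages, sex = "female", qx = gomp(1.64e-05, 0.103))
  )
}

#' Read a life table from CSV
#'
#' Expects columns `age`, `sex` (`male`/`female`), `qx` with qx in \[0, 1\].
#'
#' @param path CSV file path.
#' @return Validated life-table `data.frame`.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "sex", "qx")
  if (!all(need %in% names(lt)))
    stop("life table must have columns: ", paste(need, collapse = ", "))
  if (any(!lt$sex %in% c("male", "female")))
    stop("life table 'sex' must be 'male' or 'female'")
  if (any(!is.finite(lt$qx)) || any(lt$qx < 0 | lt$qx > 1))
    stop("life table 'qx' must be probabilities in [0, 1]")
  lt[, need]
}

# qx lookup, clamping ages beyond the table to its terminal row per sex
lookup_qx <- function(life_table, age, sex) {
  qx <- numeric(length(age))
  for (s in c("male", "female")) {
    i <- which(sex == s)
    if (!length(i)) next
    tab <- life_table[life_table$sex == s, ]
    tab <- tab[order(tab$age), ]
    a <- pmin(pmax(age[i], min(tab$age)), max(tab$age))
    qx[i] <- tab$qx[match(a, tab$age)]
  }
  qx
}

#' Whole-year life expectancy implied by a life table
#'
#' Expected number of completed years lived from `age`, computed with the
#' same accrual convention as the microsimulation (a year is counted when the
#' individual is alive at its start; no half-cycle correction), truncated at
#' `cap`. About half a year lower than a standard mid-year `ex`.
#'
#' @param life_table Life-table `data.frame` (`age`, `sex`, `qx`).
#' @param age Starting age (vectorised).
#' @param sex `"male"`/`"female"` (vectorised).
#' @param cap Age cap (default 100): no years accrue at ages > cap.
#' @return Numeric vector of expected completed years.
#' @export
life_table_expectancy <- function(life_table, age, sex, cap = 100) {
  if (nrow(life_table) == 0) stop("empty life table")
  mapply(function(a, s) {
    if (a > cap) return(0)
    q <- lookup_qx(life_table, a:cap, rep(s, cap - a + 1))
    sum(cumprod(c(1, 1 - q[-length(q)])))
  }, age, sex)
}

#' Default model parameters
#'
#' Assembles the full parameter set driving the microsimulation and the
#' cost-effectiveness analytics: treatment relative risks (SPRINT-style
#' defaults), risk-equation coefficients, post-event transition
#' probabilities, serious-adverse-event (SAE) rate, background mortality,
#' payer-perspective costs in 2017 international dollars, age-sex utilities,
#' the 3% annual discount rate, and default probabilistic/deterministic
#' sensitivity specifications. Costs, utilities and transition probabilities
#' are documented placeholders with the right orders of magnitude, not
#' estimates from any single source.
#'
#' @param life_table Life table used for background mortality
#'   (default [default_life_table()]).
#' @return A list of class `model_params`. Key components:
#' \describe{
#'   \item{rr_treatment}{relative risks, intensive vs standard, for
#'     `mi`, `stroke`, `hf`, `cvd_death`, `sae` (SAE > 1: harms increase).}
#'   \item{event_shares}{split of the 10-year general-CVD risk into primary
#'     MI / stroke / heart-failure incidence.}
#'   \item{chronic_probs}{per prior event type, annual probabilities of a
#'     further (secondary) CVD event and of CVD death, separately for the
#'     first post-event year (`*_y1`, elevated) and later years.}
#'   \item{costs, utilities}{see [cycle_cost()] and [cycle_utility()].}
#' }
#' @export
default_model_params <- function(life_table = default_life_table()) {
  p <- list(
    horizon_age_cap = 100,
    discount_rate = 0.03,
    ppp_rate = 3.54,              # yuan per Int$, 2017 PPP
    cvd_death_fraction = 0.40,    # share of all-cause mortality that is CVD
    rr_treatment = list(mi = 0.83, stroke = 0.89, hf = 0.62,
                        cvd_death = 0.57, sae = 1.88),
    risk_equation = framingham_gcvd_coefficients(),
    event_shares = list(mi = 0.30, stroke = 0.45, hf = 0.25),
    p_cvd_death_well = 0.002,     # CVD death without a preceding modeled event
    chronic_probs = list(
      mi     = list(secondary_y1 = 0.080, secondary = 0.030,
                    cvd_death_y1 = 0.080, cvd_death = 0.025),
      stroke = list(secondary_y1 = 0.090, secondary = 0.040,
                    cvd_death_y1 = 0.100, cvd_death = 0.035),
      hf     = list(secondary_y1 = 0.080, secondary = 0.035,
                    cvd_death_y1 = 0.150, cvd_death = 0.060)
    ),
    secondary_mix = list(mi = 1 / 3, stroke = 1 / 3, hf = 1 / 3),
    sae_prob_standard = 0.012,
    life_table = life_table,
    # optional: bypass the risk equations with fixed annual primary-event
    # probabilities list(mi=,stroke=,hf=) -- used for toy/validation models
    fixed_primary = NULL,
    costs = list(
      annual_drug_cost = list(intensive = 361, standard = 178),
      acute_event_cost = list(mi = 7500, stroke = 5500, hf = 4500),
      chronic_annual_cost = list(mi = 800, stroke = 1300, hf = 1000),
      sae_cost = 500
    ),
    utilities = list(
      baseline = data.frame(
        age_lo = c(45, 55, 65, 75, 85),
        male   = c(0.93, 0.91, 0.88, 0.84, 0.79),
        female = c(0.92, 0.89, 0.86, 0.81, 0.76)
      ),
      state_multiplier = list(mi = 0.90, stroke = 0.78, hf = 0.76),
      acute_multiplier = list(mi = 0.80, stroke = 0.65, hf = 0.70),
      sae_utility_value = 0.5,
      sae_duration_weeks = 1
    )
  )
  p$psa <- default_psa_spec()
  p$dsa <- default_dsa_ranges()
  class(p) <- c("model_params", "list")
  p
}

#' Default probabilistic sensitivity analysis specification
#'
#' One entry per varied parameter: the parameter path inside the
#' `model_params` list, the sampling family and its dispersion. Families
#' follow the standard support-matched choices: Beta for probabilities and
#' utilities, Gamma for costs, log-normal for relative risks.
#'
#' @return List of entries `list(path, dist, cv | sdlog)`.
#' @export
default_psa_spec <- function() {
  ln <- function(...) list(path = c(...), dist = "lognormal", sdlog = 0.12)
  ga <- function(...) list(path = c(...), dist = "gamma", cv = 0.20)
  be <- function(...) list(path = c(...), dist = "beta", cv = 0.15)
  list(
    ln("rr_treatment", "mi"), ln("rr_treatment", "stroke"),
    ln("rr_treatment", "hf"), ln("rr_treatment", "cvd_death"),
    ln("rr_treatment", "sae"),
    ga("costs", "annual_drug_cost", "intensive"),
    ga("costs", "annual_drug_cost", "standard"),
    ga("costs", "acute_event_cost", "mi"),
    ga("costs", "acute_event_cost", "stroke"),
    ga("costs", "acute_event_cost", "hf"),
    ga("costs", "chronic_annual_cost", "stroke"),
    ga("costs", "sae_cost"),
    be("sae_prob_standard"),
    be("chronic_probs", "stroke", "cvd_death"),
    be("utilities", "sae_utility_value")
  )
}

#' Default one-way (deterministic) sensitivity ranges
#'
#' Plausible low/high values per parameter, each containing the base value;
#' the set mirrors the parameters typically leading a tornado diagram in
#' intensive blood-pressure control analyses (drug cost, treatment effect on
#' CVD death and stroke, SAE cost and utility, post-stroke care cost).
#'
#' @return Named list of `c(low, high)` keyed by collapsed parameter path
#'   (`"a/b/c"`).
#' @export
default_dsa_ranges <- function() {
  list(
    "costs/annual_drug_cost/intensive" = c(180, 720),
    "rr_treatment/cvd_death"           = c(0.38, 0.85),
    "rr_treatment/stroke"              = c(0.63, 1.25),
    "costs/sae_cost"                   = c(250, 1000),
    "costs/chronic_annual_cost/stroke" = c(650, 2600),
    "utilities/sae_utility_value"      = c(0.30, 0.70),
    "rr_treatment/sae"                 = c(1.10, 3.00),
    "rr_treatment/hf"                  = c(0.41, 0.95)
  )
}

#' Get / set a parameter by path
#'
#' @param params `model_params` list.
#' @param path Character vector of nested names, or a single `"a/b/c"` string.
#' @param value Replacement value (for `param_set`).
#' @return `param_get`: the value; `param_set`: the modified params.
#' @export
param_get <- function(params, path) {
  path <- split_path(path)
  for (k in path) params <- params[[k]]
  params
}

#' @rdname param_get
#' @export
param_set <- function(params, path, value) {
  path <- split_path(path)
  params[[path]] <- value
  params
}

split_path <- function(path) {
  if (length(path) == 1 && grepl("/", path)) strsplit(path, "/")[[1]] else path
}

#' Validate model parameters
#'
#' Checks probability ranges, positivity of relative risks and costs,
#' utility bounds, discount rate, and that every deterministic
#' sensitivity range contains the base value. Stops on the first violation.
#'
#' @param params `model_params` list.
#' @return `params`, invisibly, if valid.
#' @export
validate_model_params <- function(params) {
  chk_prob <- function(x, what) {
    if (any(!is.finite(unlist(x))) || any(unlist(x) < 0 | unlist(x) > 1))
      stop(what, " must be probabilities in [0, 1]")
  }
  if (any(unlist(params$rr_treatment) <= 0)) stop("relative risks must be > 0")
  if (params$discount_rate < 0) stop("discount_rate must be >= 0")
  if (params$ppp_rate <= 0) stop("ppp_rate must be > 0")
  chk_prob(params$chronic_probs, "chronic_probs")
  chk_prob(params$sae_prob_standard, "sae_prob_standard")
  chk_prob(params$p_cvd_death_well, "p_cvd_death_well")
  chk_prob(params$event_shares, "event_shares")
  if (params$cvd_death_fraction < 0 || params$cvd_death_fraction >= 1)
    stop("cvd_death_fraction must be in [0, 1)")
  if (any(unlist(params$costs) < 0)) stop("costs must be >= 0")
  u <- params$utilities
  if (any(unlist(u$baseline[, c("male", "female")]) < 0) ||
      any(unlist(u$baseline[, c("male", "female")]) > 1))
    stop("baseline utilities must be in [0, 1]")
  if (u$sae_utility_value < 0 || u$sae_utility_value > 1)
    stop("sae_utility_value must be in [0, 1]")
  for (nm in names(params$dsa)) {
    base <- param_get(params, nm)
    rng <- params$dsa[[nm]]
    if (base < rng[1] || base > rng[2])
      stop("DSA range for '", nm, "' does not contain the base value")
  }
  invisible(params)
}

#' Read / write model parameters (YAML or JSON)
#'
#' Serialisation round-trips the full parameter list; the life table and the
#' baseline utility table are stored as column lists. Extension `.yaml`/
#' `.yml` selects YAML, `.json` JSON.
#'
#' @param path File path.
#' @param params `model_params` list (for `write_model_params`).
#' @return `read_model_params`: a validated `model_params` list.
#' @export
read_model_params <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  raw$life_table <- as.data.frame(raw$life_table, stringsAsFactors = FALSE)
  raw$utilities$baseline <- as.data.frame(raw$utilities$baseline)
  for (i in seq_along(raw$dsa)) raw$dsa[[i]] <- as.numeric(raw$dsa[[i]])
  class(raw) <- c("model_params", "list")
  validate_model_params(raw)
  raw
}

#' @rdname read_model_params
#' @export
write_model_params <- function(params, path) {
  x <- unclass(params)
  x$life_table <- as.list(x$life_table)
  x$utilities$baseline <- as.list(x$utilities$baseline)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
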