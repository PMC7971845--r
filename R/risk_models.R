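# Risk machinery: probability algebra (annualisation, relative risks in the
# hazard domain), the continuous Cox-form Framingham general-CVD risk
# function, and per-cycle hazard assembly for the microsimulation.

#' Convert a multi-year risk to a per-cycle (annual) probability
#'
#' Constant-hazard conversion: `1 - (1 - p_multi)^(1/years)`. Compounding the
#' result over `years` one-year cycles recovers `p_multi` exactly.
#'
#' @param p_multi Cumulative risk over `years` (in \[0, 1)).
#' @param years Length of the risk window (> 0).
#' @return Per-year probability.
#' @export
annualize_risk <- function(p_multi, years) {
  if (any(years <= 0)) stop("years must be > 0")
  if (any(p_multi < 0) || any(p_multi >= 1))
    stop("p_multi must be in [0, 1): a risk of 1 has infinite hazard")
  1 - (1 - p_multi)^(1 / years)
}

#' Apply a relative risk in the hazard domain
#'
#' Scales the implied event rate, not the probability:
#' `1 - (1 - p)^rr`. Keeps the result in \[0, 1) for any positive `rr`
#' (a plain multiplication would not), and composes multiplicatively:
#' applying `r1` then `r2` equals applying `r1 * r2`.
#'
#' @param p_annual Baseline per-cycle probability (in \[0, 1)).
#' @param rr Relative risk (> 0); 1 is the identity.
#' @return Adjusted per-cycle probability.
#' @export
apply_relative_risk <- function(p_annual, rr) {
  if (any(rr <= 0)) stop("rr must be > 0")
  if (any(p_annual < 0) || any(p_annual >= 1)) stop("p_annual must be in [0, 1)")
  1 - (1 - p_annual)^rr
}

# 10-year general-CVD risk, continuous Cox form, vectorised over a
# data.frame of covariates. Ages are clamped into the equation's derivation
# range [30, 74]; eligibility handles age >= 75 through its own criterion.
cox_gcvd_risk <- function(age, sex, sbp, on_bp_treatment, total_chol,
                          hdl_chol, smoker, diabetes,
                          coefs = framingham_gcvd_coefficients()) {
  if (any(total_chol <= 0) || any(hdl_chol <= 0))
    stop("cholesterol values must be positive")
  if (any(sbp <= 0)) stop("sbp must be positive")
  age <- pmin(pmax(age, 30), 74)
  risk <- numeric(length(age))
  for (s in c("male", "female")) {
    i <- which(sex == s)
    if (!length(i)) next
    cf <- coefs[[s]]
    b_sbp <- ifelse(on_bp_treatment[i], cf$ln_sbp_treated, cf$ln_sbp_untreated)
    lp <- cf$ln_age * log(age[i]) + cf$ln_tc * log(total_chol[i]) +
      cf$ln_hdl * log(hdl_chol[i]) + b_sbp * log(sbp[i]) +
      cf$smoker * as.numeric(smoker[i]) + cf$diabetes * as.numeric(diabetes[i])
    risk[i] <- 1 - cf$s0^exp(lp - cf$mean_lp)
  }
  pmin(pmax(risk, 1e-12), 1 - 1e-12)
}

# annual primary-event probabilities (mi, stroke, hf) for individuals in the
# well state at their current age, before treatment-effect adjustment.
# Either risk-equation-driven (10-year general-CVD risk split by
# event_shares, annualised) or fixed via params$fixed_primary.
primary_event_probs <- function(df, params) {
  if (!is.null(params$fixed_primary)) {
    n <- nrow(df)
    return(list(mi = rep(params$fixed_primary$mi, n),
                stroke = rep(params$fixed_primary$stroke, n),
                hf = rep(params$fixed_primary$hf, n)))
  }
  p10 <- cox_gcvd_risk(df$age, df$sex, df$sbp, df$on_bp_treatment,
                       df$total_chol, df$hdl_chol, df$smoker, df$diabetes,
                       params$risk_equation)
  sh <- params$event_shares
  list(mi = annualize_risk(p10 * sh$mi, 10),
       stroke = annualize_risk(p10 * sh$stroke, 10),
       hf = annualize_risk(p10 * sh$hf, 10))
}

# background non-CVD mortality at current age/sex: life-table all-cause qx
# times (1 - cvd_death_fraction). Ages beyond the table use its terminal row.
background_noncvd_prob <- function(age, sex, params) {
  lookup_qx(params$life_table, age, sex) * (1 - params$cvd_death_fraction)
}

rr_or_1 <- function(params, strategy, what) {
  if (strategy == "intensive") params$rr_treatment[[what]] else 1
}

#' Per-cycle hazards for one individual in the event-free state
#'
#' Assembles the competing per-cycle probabilities the simulation uses for an
#' individual currently event-free: primary MI / stroke / heart-failure
#' incidence from the risk equations (10-year risk annualised), direct CVD
#' death, background non-CVD death from the life table, and the serious
#' adverse event (SAE) probability. Under the intensive strategy each
#' component is adjusted by its treatment relative risk in the hazard domain.
#'
#' @param ind One-row `data.frame` (or list) with fields `age`, `sex`, `sbp`,
#'   `on_bp_treatment`, `total_chol`, `hdl_chol`, `smoker`, `diabetes`.
#' @param strategy `"intensive"` or `"standard"`.
#' @param params `model_params`.
#' @return List `p_mi`, `p_stroke`, `p_hf`, `p_cvd_death`, `p_noncvd_death`,
#'   `p_sae`, each a per-cycle probability.
#' @export
primary_hazards <- function(ind, strategy = c("standard", "intensive"),
                            params = default_model_params()) {
  strategy <- match.arg(strategy)
  df <- as.data.frame(ind, stringsAsFactors = FALSE)
  pe <- primary_event_probs(df, params)
  list(
    p_mi = apply_relative_risk(pe$mi, rr_or_1(params, strategy, "mi")),
    p_stroke = apply_relative_risk(pe$stroke, rr_or_1(params, strategy, "stroke")),
    p_hf = apply_relative_risk(pe$hf, rr_or_1(params, strategy, "hf")),
    p_cvd_death = apply_relative_risk(rep(params$p_cvd_death_well, nrow(df)),
                                      rr_or_1(params, strategy, "cvd_death")),
    p_noncvd_death = background_noncvd_prob(df$age, df$sex, params),
    p_sae = apply_relative_risk(rep(params$sae_prob_standard, nrow(df)),
                                rr_or_1(params, strategy, "sae"))
  )
}
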