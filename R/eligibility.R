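# SPRINT-eligibility screening: Framingham general-CVD 10-year risk,
# CKD-EPI kidney function, the sequential multistep algorithm, and the
# criterion funnel with survey-weighted national projections.

#' Framingham 10-year general cardiovascular risk
#'
#' Continuous (Cox-model) form of the sex-specific Framingham general
#' cardiovascular disease risk function:
#' `risk = 1 - S0 ^ exp(lp - mean_lp)` with the linear predictor on
#' log-transformed age, systolic blood pressure (separate coefficients when
#' treated), total and HDL cholesterol, plus smoking and diabetes
#' indicators. Ages are clamped into the derivation range \[30, 74\];
#' outside that range the score is computed at the nearest boundary age
#' (the age >= 75 eligibility criterion makes the clamp immaterial for
#' screening).
#'
#' @param ind `data.frame` (any number of rows) or list with fields `age`,
#'   `sex`, `sbp`, `on_bp_treatment`, `total_chol`, `hdl_chol`, `smoker`,
#'   `diabetes`.
#' @param coefs Coefficient tables, default
#'   [framingham_gcvd_coefficients()].
#' @return Numeric vector of 10-year risks in (0, 1); strictly increasing in
#'   SBP, all else fixed.
#' @export
framingham_cvd_risk <- function(ind, coefs = framingham_gcvd_coefficients()) {
  df <- as.data.frame(ind, stringsAsFactors = FALSE)
  need <- c("age", "sex", "sbp", "on_bp_treatment", "total_chol",
            "hdl_chol", "smoker", "diabetes")
  miss <- need[vapply(need, function(k) is.null(df[[k]]) || anyNA(df[[k]]),
                      logical(1))]
  if (length(miss))
    stop("missing covariates for Framingham risk: ",
         paste(miss, collapse = ", "))
  cox_gcvd_risk(df$age, df$sex, df$sbp, df$on_bp_treatment, df$total_chol,
                df$hdl_chol, df$smoker, df$diabetes, coefs)
}

#' Estimated glomerular filtration rate (CKD-EPI 2009, no race term)
#'
#' `eGFR = 141 (or 144 for women) * min(Scr/k, 1)^a * max(Scr/k, 1)^-1.209
#'  * 0.993^age * 1.018[female]` with `k = 0.7` (women) / `0.9` (men) and
#' `a = -0.329` (women) / `-0.411` (men). Folding the female factor 1.018
#' into the female intercept gives the familiar 144. Strictly decreasing in
#' creatinine.
#'
#' @param creatinine Serum creatinine, mg/dL (> 0).
#' @param age Age in years.
#' @param sex `"male"`/`"female"`.
#' @return eGFR in mL/min/1.73 m^2.
#' @export
estimate_egfr <- function(creatinine, age, sex) {
  if (any(is.na(creatinine)) || any(creatinine <= 0))
    stop("creatinine must be positive")
  female <- sex == "female"
  k <- ifelse(female, 0.7, 0.9)
  a <- ifelse(female, -0.329, -0.411)
  r <- creatinine / k
  141 * pmin(r, 1)^a * pmax(r, 1)^(-1.209) * 0.993^age *
    ifelse(female, 1.018, 1)
}

# eGFR with passthrough precedence: a recorded egfr value wins over
# derivation from creatinine.
resolve_egfr <- function(pop) {
  eg <- pop$egfr
  if (is.null(eg)) eg <- rep(NA_real_, nrow(pop))
  need <- is.na(eg)
  if (any(need)) {
    if (is.null(pop$creatinine) || anyNA(pop$creatinine[need]))
      stop("eGFR unavailable and creatinine missing for some individuals ",
           "(risk-condition step)")
    eg[need] <- estimate_egfr(pop$creatinine[need], pop$age[need],
                              pop$sex[need])
  }
  eg
}

#' Screen a population for SPRINT eligibility
#'
#' Applies the multistep algorithm in order: (1) age >= 50; (2) SBP within
#' the trial window -- by default the relaxed criterion 130-180 mm Hg on any
#' number of medication classes (used because survey data typically lack
#' class counts), optionally the original medication-stratified windows
#' (130-180 on <= 1 class, 130-170 on <= 2, 130-160 on <= 3, 130-150 on
#' <= 4); (3) at least one high-CVD-risk condition: history of coronary
#' heart disease, eGFR 20-59 mL/min/1.73 m^2, Framingham 10-year risk
#' >= 15%, or age >= 75; (4) no exclusion: diabetes, history of stroke,
#' heart failure, or end-stage renal disease. All bounds are inclusive.
#' All four risk conditions are evaluated for every individual even after
#' one is met.
#'
#' @param pop Population `data.frame`.
#' @param strict_med_classes If `TRUE`, use the medication-stratified SBP
#'   windows (requires `n_bp_med_classes`); default `FALSE` (relaxed rule).
#' @param coefs Framingham coefficient tables.
#' @return `data.frame` with one row per individual: `eligible`,
#'   `failed_step` (ordinal of the first failed criterion, `NA` if
#'   eligible), `framingham_risk`, the four risk-condition indicators
#'   (`cond_chd_history`, `cond_egfr_20_59`, `cond_framingham_ge_15`,
#'   `cond_age_ge_75`) and the four exclusion indicators (`excl_diabetes`,
#'   `excl_stroke_history`, `excl_heart_failure`, `excl_esrd`).
#' @export
screen_population <- function(pop, strict_med_classes = FALSE,
                              coefs = framingham_gcvd_coefficients()) {
  need <- c("age", "sex", "sbp", "on_bp_treatment", "total_chol", "hdl_chol",
            "smoker", "diabetes", "hist_chd", "hist_stroke", "hist_hf",
            "esrd")
  for (k in need)
    if (is.null(pop[[k]]) || anyNA(pop[[k]]))
      stop("missing required covariate '", k, "' for eligibility screening")

  step1 <- pop$age >= 50
  if (strict_med_classes) {
    nmed <- pop$n_bp_med_classes
    if (is.null(nmed) || anyNA(nmed))
      stop("missing required covariate 'n_bp_med_classes' for the ",
           "medication-stratified SBP window (step 2)")
    hi <- ifelse(nmed <= 1, 180, ifelse(nmed <= 2, 170,
                 ifelse(nmed <= 3, 160, ifelse(nmed <= 4, 150, -Inf))))
    step2 <- pop$sbp >= 130 & pop$sbp <= hi
  } else {
    step2 <- pop$sbp >= 130 & pop$sbp <= 180
  }
  fr <- framingham_cvd_risk(pop, coefs)
  eg <- resolve_egfr(pop)
  cond <- cbind(
    chd_history = pop$hist_chd,
    egfr_20_59 = eg >= 20 & eg <= 59,
    framingham_ge_15 = fr >= 0.15,
    age_ge_75 = pop$age >= 75
  )
  step3 <- rowSums(cond) > 0
  excl <- cbind(
    diabetes = pop$diabetes,
    stroke_history = pop$hist_stroke,
    heart_failure = pop$hist_hf,
    esrd = pop$esrd
  )
  step4 <- rowSums(excl) == 0

  eligible <- step1 & step2 & step3 & step4
  failed_step <- rep(NA_integer_, nrow(pop))
  failed_step[!step4] <- 4L
  failed_step[!step3] <- 3L
  failed_step[!step2] <- 2L
  failed_step[!step1] <- 1L

  data.frame(
    eligible = eligible, failed_step = failed_step, framingham_risk = fr,
    cond_chd_history = cond[, "chd_history"],
    cond_egfr_20_59 = cond[, "egfr_20_59"],
    cond_framingham_ge_15 = cond[, "framingham_ge_15"],
    cond_age_ge_75 = cond[, "age_ge_75"],
    excl_diabetes = excl[, "diabetes"],
    excl_stroke_history = excl[, "stroke_history"],
    excl_heart_failure = excl[, "heart_failure"],
    excl_esrd = excl[, "esrd"]
  )
}

#' SPRINT eligibility for a single individual
#'
#' Single-individual wrapper around [screen_population()] returning the
#' structured eligibility result.
#'
#' @param ind One-row `data.frame` or list of covariates.
#' @param strict_med_classes See [screen_population()].
#' @return List `eligible`, `failed_step` (`NA` when eligible),
#'   `risk_conditions_met` (character subset), `exclusions_hit` (character
#'   subset), `framingham_risk`.
#' @export
sprint_eligible <- function(ind, strict_med_classes = FALSE) {
  df <- as.data.frame(ind, stringsAsFactors = FALSE)
  s <- screen_population(df, strict_med_classes = strict_med_classes)
  conds <- c("chd_history", "egfr_20_59", "framingham_ge_15", "age_ge_75")
  excls <- c("diabetes", "stroke_history", "heart_failure", "esrd")
  list(
    eligible = s$eligible[1],
    failed_step = s$failed_step[1],
    risk_conditions_met = conds[unlist(s[1, paste0("cond_", conds)])],
    exclusions_hit = excls[unlist(s[1, paste0("excl_", excls)])],
    framingham_risk = s$framingham_risk[1]
  )
}

#' Sequential eligibility funnel with national projections
#'
#' Weighted proportion, 95% CI, and represented millions
#' (`proportion * population_scale`, valid when weights are
#' mean-normalised) for each sequential criterion -- all adults, age >= 50,
#' SBP in window, >= 1 risk condition, no exclusion (= eligible) -- followed
#' by subgroup rows among the eligible: hypertensive (SBP >= 140 or
#' DBP >= 90 or on treatment), non-hypertensive with SBP 130-139, treated
#' hypertensive, and untreated individuals.
#'
#' @param pop Population `data.frame`.
#' @param population_scale Millions of people the (mean-1) weights
#'   represent.
#' @param strict_med_classes See [screen_population()].
#' @return `data.frame` of class `funnel_table` with columns `label`,
#'   `proportion`, `se`, `ci_low`, `ci_high`, `millions`.
#' @export
build_funnel <- function(pop, population_scale, strict_med_classes = FALSE) {
  if (nrow(pop) == 0) stop("cannot build a funnel from an empty population")
  s <- screen_population(pop, strict_med_classes = strict_med_classes)
  step1 <- is.na(s$failed_step) | s$failed_step > 1
  step2 <- is.na(s$failed_step) | s$failed_step > 2
  step3 <- is.na(s$failed_step) | s$failed_step > 3
  elig <- s$eligible
  htn <- pop$sbp >= 140 | pop$dbp >= 90 | pop$on_bp_treatment
  rows <- list(
    "all adults (>= 45 y)" = rep(TRUE, nrow(pop)),
    "age >= 50 y" = step1,
    "SBP in eligible window" = step2,
    ">= 1 high-CVD-risk condition" = step3,
    "no exclusion (SPRINT eligible)" = elig,
    "eligible, hypertensive" = elig & htn,
    "eligible, SBP 130-139 without hypertension" =
      elig & !htn & pop$sbp >= 130 & pop$sbp < 140,
    "eligible, treated hypertensive" = elig & htn & pop$on_bp_treatment,
    "eligible, untreated" = elig & !pop$on_bp_treatment
  )
  out <- do.call(rbind, lapply(names(rows), function(lab) {
    wp <- weighted_proportion(pop, rows[[lab]])
    data.frame(label = lab, proportion = wp$proportion, se = wp$se,
               ci_low = wp$ci_low, ci_high = wp$ci_high,
               millions = wp$proportion * population_scale)
  }))
  rownames(out) <- NULL
  class(out) <- c("funnel_table", "data.frame")
  out
}
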