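# Shared fixtures: hand-built individuals and reduced ("toy") model
# parameterisations whose behaviour has closed-form oracles.

mk_ind <- function(age = 60, sex = "male", sbp = 150, dbp = 85,
                   trt = FALSE, smoker = FALSE, tc = 185, hdl = 48,
                   cr = 0.9, egfr = NA_real_, chd = FALSE, stroke = FALSE,
                   hf = FALSE, dm = FALSE, esrd = FALSE, w = 1, nmed = 0L,
                   id = "x1") {
  data.frame(id = id, age = age, sex = sex, sbp = sbp, dbp = dbp,
             on_bp_treatment = trt, n_bp_med_classes = nmed,
             smoker = smoker, total_chol = tc, hdl_chol = hdl,
             creatinine = cr, egfr = egfr, hist_chd = chd,
             hist_stroke = stroke, hist_hf = hf, diabetes = dm,
             esrd = esrd, survey_weight = w, stringsAsFactors = FALSE)
}

flat_life_table <- function(q, ages = 0:120) {
  rbind(data.frame(age = ages, sex = "male", qx = q),
        data.frame(age = ages, sex = "female", qx = q))
}

# time-homogeneous reduced model: fixed primary-event probabilities, flat
# background mortality, single utility band, optional zeroed economics.
# Oracles (geometric life expectancy, matrix-power cohort values) match this
# configuration exactly.
toy_params <- function(q = 0, p_mi = 0, p_stroke = 0, p_hf = 0,
                       p_cvd_well = 0, sae = 0, cap = 100, discount = 0,
                       drug_i = 0, drug_s = 0, u_base = 1,
                       chronic = list(secondary_y1 = 0, secondary = 0,
                                      cvd_death_y1 = 0, cvd_death = 0),
                       acute_cost = 0, chronic_cost = 0, sae_cost = 0,
                       rr = list(mi = 1, stroke = 1, hf = 1,
                                 cvd_death = 1, sae = 1)) {
  p <- default_model_params(life_table = flat_life_table(q))
  p$cvd_death_fraction <- 0            # flat qx is taken as-is (non-CVD)
  p$fixed_primary <- list(mi = p_mi, stroke = p_stroke, hf = p_hf)
  p$p_cvd_death_well <- p_cvd_well
  p$sae_prob_standard <- sae
  p$horizon_age_cap <- cap
  p$discount_rate <- discount
  p$rr_treatment <- rr
  p$chronic_probs <- list(mi = chronic, stroke = chronic, hf = chronic)
  p$costs$annual_drug_cost <- list(intensive = drug_i, standard = drug_s)
  p$costs$acute_event_cost <- list(mi = acute_cost, stroke = acute_cost,
                                   hf = acute_cost)
  p$costs$chronic_annual_cost <- list(mi = chronic_cost, stroke = chronic_cost,
                                      hf = chronic_cost)
  p$costs$sae_cost <- sae_cost
  p$utilities$baseline <- data.frame(age_lo = 0, male = u_base,
                                     female = u_base)
  p$dsa <- list()                      # base values changed; ranges invalid
  p
}

# small deterministic population for funnel / IO tests
six_person_pop <- function() {
  rbind(
    mk_ind(id = "a", age = 49, sbp = 150),                 # fails age
    mk_ind(id = "b", age = 60, sbp = 125),                 # fails SBP window
    mk_ind(id = "c", age = 60, sbp = 150, tc = 150, hdl = 70,
           cr = 0.8),                                      # no risk condition
    mk_ind(id = "d", age = 66, sbp = 150, smoker = TRUE, dm = TRUE),
                                                           # excluded: diabetes
    mk_ind(id = "e", age = 80, sbp = 135, cr = 0.8),       # eligible via age
    mk_ind(id = "f", age = 60, sbp = 150, egfr = 45)       # eligible via eGFR
  )
}
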