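# Framingham risk, CKD-EPI eGFR, the multistep screen, and the funnel

# independent re-implementation of the published general-CVD risk function,
# written as literal spreadsheet arithmetic (not via the package machinery)
oracle_framingham <- function(age, sex, sbp, treated, tc, hdl, smoke, dm) {
  if (sex == "male") {
    lp <- 3.06117 * log(age) + 1.12370 * log(tc) - 0.93263 * log(hdl) +
      (if (treated) 1.99881 else 1.93303) * log(sbp) +
      0.65451 * smoke + 0.57367 * dm
    1 - 0.88936^exp(lp - 23.9802)
  } else {
    lp <- 2.32888 * log(age) + 1.20904 * log(tc) - 0.70833 * log(hdl) +
      (if (treated) 2.82263 else 2.76157) * log(sbp) +
      0.52873 * smoke + 0.69154 * dm
    1 - 0.95012^exp(lp - 26.1931)
  }
}

test_that("Framingham risk matches the independent oracle to 4 decimals", {
  profiles <- list(
    list(age = 61, sex = "male", sbp = 130, trt = FALSE, tc = 180,
         hdl = 47, smoker = FALSE, dm = FALSE),
    list(age = 55, sex = "female", sbp = 145, trt = TRUE, tc = 210,
         hdl = 55, smoker = TRUE, dm = FALSE),
    list(age = 70, sex = "male", sbp = 160, trt = TRUE, tc = 200,
         hdl = 40, smoker = TRUE, dm = TRUE)
  )
  for (p in profiles) {
    got <- framingham_cvd_risk(mk_ind(age = p$age, sex = p$sex, sbp = p$sbp,
                                      trt = p$trt, tc = p$tc, hdl = p$hdl,
                                      smoker = p$smoker, dm = p$dm))
    want <- oracle_framingham(p$age, p$sex, p$sbp, p$trt, p$tc, p$hdl,
                              p$smoker, p$dm)
    expect_equal(got, want, tolerance = 5e-5)
  }
})

test_that("Framingham risk is monotone in SBP, bounded, and validated", {
  lo <- framingham_cvd_risk(mk_ind(sbp = 120))
  hi <- framingham_cvd_risk(mk_ind(sbp = 160))
  expect_gt(hi, lo)
  # range (0,1) over a covariate sweep
  set.seed(1)
  for (k in 1:50) {
    r <- framingham_cvd_risk(mk_ind(
      age = sample(45:95, 1), sex = sample(c("male", "female"), 1),
      sbp = runif(1, 90, 220), trt = runif(1) < 0.5,
      tc = runif(1, 100, 320), hdl = runif(1, 25, 90),
      smoker = runif(1) < 0.5, dm = runif(1) < 0.2))
    expect_true(r > 0 && r < 1)
  }
  # age clamped into [30, 74]: 74 and 90 give the same score
  expect_equal(framingham_cvd_risk(mk_ind(age = 90)),
               framingham_cvd_risk(mk_ind(age = 74)))
  expect_error(framingham_cvd_risk(mk_ind(tc = -1)), "positive")
  expect_error(framingham_cvd_risk(mk_ind(tc = NA)), "missing")
})

test_that("CKD-EPI eGFR matches hand computation and is monotone", {
  # female, 60 y, creatinine 1.1 (> k = 0.7):
  # 141 * (1.1/0.7)^-1.209 * 0.993^60 * 1.018, literal arithmetic
  want <- 141 * (1.1 / 0.7)^(-1.209) * 0.993^60 * 1.018
  expect_equal(estimate_egfr(1.1, 60, "female"), want, tolerance = 1e-10)
  expect_equal(round(estimate_egfr(1.1, 60, "female"), 1), round(want, 1))

  # male below/above the knee, doubling creatinine lowers eGFR
  expect_lt(estimate_egfr(1.8, 60, "male"), estimate_egfr(0.9, 60, "male"))
  expect_lt(estimate_egfr(1.0, 60, "male"), estimate_egfr(0.5, 60, "male"))
  expect_error(estimate_egfr(0, 60, "male"), "positive")

  # passthrough: a recorded eGFR wins over creatinine
  r <- sprint_eligible(mk_ind(age = 60, sbp = 150, egfr = 55, cr = 0.5))
  expect_true("egfr_20_59" %in% r$risk_conditions_met)
})

test_that("the multistep algorithm applies criteria in order", {
  r <- sprint_eligible(mk_ind(age = 49, sbp = 150))
  expect_false(r$eligible); expect_equal(r$failed_step, 1L)

  r <- sprint_eligible(mk_ind(age = 80, sbp = 135, cr = 0.8, tc = 150,
                              hdl = 70))
  expect_true(r$eligible)
  expect_true("age_ge_75" %in% r$risk_conditions_met)
  expect_false("egfr_20_59" %in% r$risk_conditions_met)

  r <- sprint_eligible(mk_ind(age = 66, sbp = 150, smoker = TRUE, dm = TRUE))
  expect_false(r$eligible)
  expect_equal(r$failed_step, 4L)
  expect_equal(r$exclusions_hit, "diabetes")
  expect_gte(r$framingham_risk, 0.15)  # risk conditions still evaluated
  expect_true("framingham_ge_15" %in% r$risk_conditions_met)

  expect_error(sprint_eligible(mk_ind(sbp = NA)), "sbp")
})

test_that("eligibility boundaries are inclusive as printed", {
  base <- function(...) mk_ind(age = 60, egfr = 45, ...)  # risk cond via eGFR
  expect_true(sprint_eligible(base(sbp = 130))$eligible)
  expect_true(sprint_eligible(base(sbp = 180))$eligible)
  expect_equal(sprint_eligible(base(sbp = 129.9))$failed_step, 2L)
  expect_equal(sprint_eligible(base(sbp = 180.1))$failed_step, 2L)

  eg <- function(v) sprint_eligible(mk_ind(age = 60, sbp = 150, egfr = v,
                                           tc = 150, hdl = 70))
  expect_true("egfr_20_59" %in% eg(20)$risk_conditions_met)
  expect_true("egfr_20_59" %in% eg(59)$risk_conditions_met)
  expect_false("egfr_20_59" %in% eg(19.99)$risk_conditions_met)
  expect_false("egfr_20_59" %in% eg(59.01)$risk_conditions_met)

  expect_equal(sprint_eligible(mk_ind(age = 49.9, sbp = 150))$failed_step, 1L)
  expect_true("age_ge_75" %in%
                sprint_eligible(mk_ind(age = 75, sbp = 150,
                                       egfr = 90))$risk_conditions_met)

  # Framingham >= 0.15 is inclusive: coefficient table engineered so the
  # score is exactly 1 - s0 = 0.15 (all betas 0, mean_lp 0)
  mkcoef <- function(s0) {
    cf <- list(ln_age = 0, ln_tc = 0, ln_hdl = 0, ln_sbp_untreated = 0,
               ln_sbp_treated = 0, smoker = 0, diabetes = 0,
               s0 = s0, mean_lp = 0)
    list(male = cf, female = cf)
  }
  s <- screen_population(mk_ind(age = 60, sbp = 150, tc = 150, hdl = 70,
                                cr = 0.8), coefs = mkcoef(0.85))
  expect_equal(s$framingham_risk, 0.15)
  expect_true(s$cond_framingham_ge_15)
  s <- screen_population(mk_ind(age = 60, sbp = 150, tc = 150, hdl = 70,
                                cr = 0.8), coefs = mkcoef(0.8501))
  expect_false(s$cond_framingham_ge_15)
})

test_that("criteria are conjunctive: eligibility is order-independent", {
  pop <- generate_population(population_spec(2000, seed = 13))
  s <- screen_population(pop)
  # brute-force conjunction, evaluated without any sequencing
  conj <- pop$age >= 50 & pop$sbp >= 130 & pop$sbp <= 180 &
    (pop$hist_chd | (s$framingham_risk >= 0.15) | pop$age >= 75 |
       s$cond_egfr_20_59) &
    !(pop$diabetes | pop$hist_stroke | pop$hist_hf | pop$esrd)
  expect_equal(s$eligible, conj)
})

test_that("medication-stratified SBP windows work behind the flag", {
  ind <- function(nmed, sbp) mk_ind(age = 60, sbp = sbp, egfr = 45,
                                    trt = nmed > 0, nmed = nmed)
  expect_true(sprint_eligible(ind(1, 175), strict_med_classes = TRUE)$eligible)
  expect_equal(sprint_eligible(ind(2, 175),
                               strict_med_classes = TRUE)$failed_step, 2L)
  expect_true(sprint_eligible(ind(2, 170), strict_med_classes = TRUE)$eligible)
  expect_true(sprint_eligible(ind(4, 150), strict_med_classes = TRUE)$eligible)
  expect_equal(sprint_eligible(ind(5, 140),
                               strict_med_classes = TRUE)$failed_step, 2L)
  # relaxed rule ignores the class count entirely
  expect_true(sprint_eligible(ind(5, 175))$eligible)
})

test_that("funnel matches a hand tally and is monotone", {
  pop <- six_person_pop()
  fun <- build_funnel(pop, population_scale = 6)
  seq_rows <- fun$millions[1:5]
  expect_equal(seq_rows, c(6, 5, 4, 3, 2))
  expect_true(all(diff(seq_rows) <= 0))

  # everyone-eligible population: all sequential rows equal the total
  allpass <- do.call(rbind, lapply(1:4, function(i)
    mk_ind(id = paste0("p", i), age = 80, sbp = 140, cr = 0.8)))
  fun2 <- build_funnel(allpass, population_scale = 10)
  expect_true(all(fun2$millions[1:5] == 10))

  # random population: monotone funnel, CI ordered
  pop <- generate_population(population_spec(3000, seed = 17))
  fun3 <- build_funnel(pop, population_scale = 523)
  expect_true(all(diff(fun3$millions[1:5]) <= 1e-9))
  expect_true(all(fun3$ci_low <= fun3$proportion + 1e-12) &&
                all(fun3$proportion <= fun3$ci_high + 1e-12))
  # soft plausibility: weighted eligible share in a 15-30% band (logged)
  elig_share <- fun3$proportion[5]
  message(sprintf("weighted SPRINT-eligible share: %.1f%%", 100 * elig_share))
  expect_error(build_funnel(pop[0, ], 1), "empty")
})
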