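# ICER quadrants, tornado, PSA, CEAC, subgroups

test_that("icer covers all nine sign combinations", {
  cases <- list(
    list(1000, 0.1, "icer", 10000),
    list(1000, 0, "undefined_ratio", NA),
    list(1000, -0.1, "dominated", NA),
    list(0, 0.1, "dominant", NA),
    list(0, 0, "equivalence", NA),
    list(0, -0.1, "dominated", NA),
    list(-5, 0.2, "dominant", NA),
    list(-5, 0, "undefined_ratio", NA),
    list(-5, -0.2, "southwest", 25)
  )
  for (cs in cases) {
    r <- icer(cs[[1]], cs[[2]])
    expect_equal(r$label, cs[[3]])
    if (is.na(cs[[4]])) expect_true(is.na(r$value))
    else expect_equal(r$value, cs[[4]])
  }
  expect_error(icer(NaN, 1), "finite")
})

test_that("population scaling is plain multiplication", {
  expect_equal(scale_to_population(0, 116.2), 0)
  expect_equal(scale_to_population(0.01, 50), 0.5)
  expect_error(scale_to_population(0.01, 0), "eligible_millions")
})

test_that("tornado rows reflect only the varied parameter (CRN)", {
  params <- toy_params(q = 0.05, p_mi = 0.05, p_stroke = 0.04, p_hf = 0.02,
                       p_cvd_well = 0.01, discount = 0.03,
                       drug_i = 300, drug_s = 120, u_base = 0.85,
                       acute_cost = 5000, chronic_cost = 800,
                       chronic = list(secondary_y1 = 0.08, secondary = 0.03,
                                      cvd_death_y1 = 0.1, cvd_death = 0.04),
                       rr = list(mi = 0.8, stroke = 0.9, hf = 0.7,
                                 cvd_death = 0.6, sae = 1))
  cohort <- bootstrap_individuals(generate_population(population_spec(
    150, seed = 2)), 250, seed = 3)
  base <- compare_strategies(cohort, params, seed = 4)$summary$icer$value

  # zero-width range reproduces the base ICER exactly
  tor <- one_way_sensitivity(cohort, params,
                             dsa_ranges = list("rr_treatment/cvd_death" =
                                                 c(0.6, 0.6)), seed = 4)
  expect_equal(tor$icer_low, base)
  expect_equal(tor$icer_high, base)
  expect_equal(attr(tor, "base_icer"), base)

  # two-parameter toy table matches brute-force re-runs, tornado-ordered
  rng <- list("costs/annual_drug_cost/intensive" = c(150, 900),
              "rr_treatment/cvd_death" = c(0.45, 0.95))
  tor <- one_way_sensitivity(cohort, params, dsa_ranges = rng, seed = 4)
  for (i in seq_len(nrow(tor))) {
    nm <- tor$parameter[i]
    for (side in c("low", "high")) {
      p2 <- param_set(params, nm, rng[[nm]][if (side == "low") 1 else 2])
      want <- compare_strategies(cohort, p2, seed = 4)$summary$icer$value
      expect_equal(tor[[paste0("icer_", side)]][i], want)
    }
  }
  expect_true(all(diff(tor$spread) <= 0))

  # raising the intensive drug cost cannot lower the ICER
  expect_gte(tor$icer_high[tor$parameter ==
                             "costs/annual_drug_cost/intensive"],
             tor$icer_low[tor$parameter ==
                            "costs/annual_drug_cost/intensive"])

  expect_error(one_way_sensitivity(cohort, params,
                                   dsa_ranges = list("rr_treatment/mi" =
                                                       c(0.9, 0.95)),
                                   seed = 4),
               "excludes the base value")
})

test_that("degenerate PSA distributions collapse to the base case", {
  params <- toy_params(q = 0.05, p_mi = 0.05, p_stroke = 0.03, p_hf = 0.02,
                       p_cvd_well = 0.01, drug_i = 300, drug_s = 120,
                       u_base = 0.85, acute_cost = 3000,
                       chronic = list(secondary_y1 = 0.05, secondary = 0.02,
                                      cvd_death_y1 = 0.08, cvd_death = 0.03),
                       rr = list(mi = 0.8, stroke = 0.9, hf = 0.7,
                                 cvd_death = 0.6, sae = 1))
  params$psa <- list(
    list(path = c("rr_treatment", "cvd_death"), dist = "lognormal",
         sdlog = 0),
    list(path = c("costs", "annual_drug_cost", "intensive"), dist = "gamma",
         cv = 0))
  cohort <- bootstrap_individuals(generate_population(population_spec(
    100, seed = 5)), 150, seed = 6)
  base <- compare_strategies(cohort, params, seed = 7)$summary
  sam <- psa(cohort, params, n_runs = 5, seed = 7)
  # parameters fixed at base; only the microsimulation streams differ by run
  for (k in 1:5) {
    run_k <- compare_strategies(cohort, params, seed = 7, run = k)$summary
    expect_equal(sam$d_cost[k], run_k$d_cost)
    expect_equal(sam$d_qaly[k], run_k$d_qaly)
  }
  expect_identical(psa(cohort, params, n_runs = 5, seed = 7), sam)

  expect_error(psa(cohort, param_set(params, "psa",
                                     list(list(path = "sae_prob_standard",
                                               dist = "triangular", cv = 1))),
                   n_runs = 2, seed = 1),
               "unsupported")
})

test_that("PSA draws have the specified moments", {
  params <- default_model_params()
  params$psa <- list(list(path = "sae_prob_standard", dist = "beta",
                          cv = 0.15))
  params$fixed_primary <- list(mi = 0, stroke = 0, hf = 0)
  params$life_table <- flat_life_table(0.95) # near-certain death: runs cheap
  params$cvd_death_fraction <- 0
  params$p_cvd_death_well <- 0
  params$dsa <- list()
  cohort <- mk_ind(age = 99)
  sam <- psa(cohort, params, n_runs = 1000, seed = 9)
  draws <- vapply(attr(sam, "sampled"), `[[`, numeric(1),
                  "sae_prob_standard")
  base <- params$sae_prob_standard
  se <- 0.15 * base / sqrt(1000)
  expect_lt(abs(mean(draws) - base), 3 * se)
  expect_true(all(draws > 0 & draws < 1))
})

test_that("CEAC follows the net-monetary-benefit rule", {
  good <- data.frame(d_cost = c(-10, -5, -1), d_qaly = c(0.1, 0.2, 0.3))
  cc <- ceac(good, c(0, 1000, 50000))
  expect_true(all(cc$probability == 1))

  mixed <- data.frame(d_cost = c(-100, 50, 200, 400),
                      d_qaly = c(0.01, 0.01, 0.02, -0.01))
  expect_equal(ceac(mixed, 0)$probability, 0.25)   # lambda 0: P(dCost < 0)
  # hand enumeration at lambda = 10000:
  # NMB = 100+100, 100-50, 200-200, -100-400 -> positive for 2 of 4
  expect_equal(ceac(mixed, 10000)$probability, 0.5)
  # all dQALY > 0 implies a non-decreasing curve in lambda
  pos <- data.frame(d_cost = rnorm(50, 100, 200),
                    d_qaly = abs(rnorm(50, 0.1, 0.1)) + 1e-6)
  curve <- ceac(pos, seq(0, 60000, by = 5000))
  expect_true(all(diff(curve$probability) >= 0))
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
  expect_error(ceac(good[0, ], 1), "samples")
})

test_that("cea_summary is internally consistent with ceac", {
  params <- toy_params(q = 0.05, p_mi = 0.05, p_stroke = 0.03, p_hf = 0.02,
                       p_cvd_well = 0.01, drug_i = 300, drug_s = 120,
                       u_base = 0.85, acute_cost = 3000,
                       chronic = list(secondary_y1 = 0.05, secondary = 0.02,
                                      cvd_death_y1 = 0.08, cvd_death = 0.03),
                       rr = list(mi = 0.8, stroke = 0.9, hf = 0.7,
                                 cvd_death = 0.6, sae = 1))
  params$psa <- list(list(path = c("rr_treatment", "cvd_death"),
                          dist = "lognormal", sdlog = 0.2))
  cohort <- bootstrap_individuals(generate_population(population_spec(
    80, seed = 8)), 100, seed = 9)
  cmp <- compare_strategies(cohort, params, seed = 10)
  sam <- psa(cohort, params, n_runs = 40, seed = 10)
  res <- cea_summary(cmp, sam)
  expect_equal(unname(res$prob_ce),
               ceac(sam, unname(threshold_spec()))$probability)
  expect_lte(res$d_cost_lo, res$d_cost_hi)
  expect_lte(res$d_qaly_lo, res$d_qaly_hi)
  expect_equal(res$d_cost, cmp$summary$d_cost)
  expect_equal(threshold_spec(), c(`1x_gdp` = 16782, `2x_gdp` = 33564))
})

test_that("subgroup analysis partitions and reproduces the pipeline", {
  pop <- generate_population(population_spec(400, seed = 11))
  s <- screen_population(pop)
  elig <- pop[s$eligible, ]
  defs <- default_subgroups()
  m <- defs$male(elig); f <- defs$female(elig)
  expect_equal(sum(m) + sum(f), nrow(elig))   # sex partitions the cohort
  expect_true(all(xor(m, f)))

  params <- toy_params(q = 0.05, p_mi = 0.04, p_stroke = 0.03, p_hf = 0.02,
                       p_cvd_well = 0.01, drug_i = 250, drug_s = 100,
                       u_base = 0.85, acute_cost = 2000,
                       chronic = list(secondary_y1 = 0.05, secondary = 0.02,
                                      cvd_death_y1 = 0.08, cvd_death = 0.03),
                       rr = list(mi = 0.8, stroke = 0.9, hf = 0.7,
                                 cvd_death = 0.6, sae = 1))
  params$psa <- list(list(path = c("rr_treatment", "cvd_death"),
                          dist = "lognormal", sdlog = 0.2))
  res <- subgroup_analysis(elig, params,
                           subgroup_defs = defs[c("overall", "male",
                                                  "female")],
                           seed = 12, n_boot = 120, n_psa = 8)
  expect_named(res, c("overall", "male", "female"))
  for (r in res) expect_s3_class(r, "cea_result")

  # the 'everyone' subgroup equals a manual run with the derived seed
  sub_seed <- as.integer((as.double(12) * 131 + 1 * 104729) %% 2147483647)
  cohort <- bootstrap_individuals(elig, 120, sub_seed)
  want <- cea_summary(compare_strategies(cohort, params, seed = sub_seed),
                      psa(cohort, params, n_runs = 8, seed = sub_seed))
  expect_equal(res$overall, want)

  expect_warning(
    subgroup_analysis(elig, params,
                      subgroup_defs = list(none = function(p)
                        rep(FALSE, nrow(p))),
                      seed = 1, n_boot = 10, n_psa = 2),
    "empty")
})
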