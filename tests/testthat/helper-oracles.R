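# Independent analytic oracle: cohort (matrix-power) evaluation of a
# time-homogeneous parameterisation under the documented cycle convention.
# Hand-coded from the model description -- it shares no code with the
# simulation engine. Valid when the life table is flat, the utility table
# has a single band, and primary-event probabilities are fixed
# (params$fixed_primary), so nothing depends on age.
#
# States: 1 well, 2 acute_mi, 3 post_mi, 4 acute_stroke, 5 post_stroke,
#         6 acute_hf, 7 post_hf, 8 cvd_death, 9 noncvd_death.

markov_oracle <- function(params, age0, sex = "male",
                          strategy = "standard") {
  rr <- function(w) if (strategy == "intensive") params$rr_treatment[[w]] else 1
  adj <- function(p, r) 1 - (1 - p)^r
  q <- params$life_table$qx[1] * (1 - params$cvd_death_fraction)
  ev <- c("mi", "stroke", "hf")
  acute_of <- c(mi = 2, stroke = 4, hf = 6)

  P <- matrix(0, 9, 9)
  fill <- function(from, p_ev, p_cvd, to_continue) {
    p <- c(p_ev, p_cvd, q)
    if (sum(p) > 1) p <- p / sum(p)
    P[from, c(2, 4, 6)] <<- p[1:3]
    P[from, 8] <<- p[4]
    P[from, 9] <<- p[5]
    P[from, to_continue] <<- 1 - sum(p)
  }
  fp <- params$fixed_primary
  fill(1, c(adj(fp$mi, rr("mi")), adj(fp$stroke, rr("stroke")),
            adj(fp$hf, rr("hf"))),
       adj(params$p_cvd_death_well, rr("cvd_death")), 1)
  for (e in ev) {
    cp <- params$chronic_probs[[e]]
    sec <- function(p_sec, skip = NULL) vapply(ev, function(k)
      if (identical(k, skip)) 0 else
        adj(p_sec * params$secondary_mix[[k]], rr(k)), numeric(1))
    # out of the acute year, a same-type recurrence is not a separate event
    fill(acute_of[[e]], sec(cp$secondary_y1, skip = e),
         adj(cp$cvd_death_y1, rr("cvd_death")), acute_of[[e]] + 1)
    fill(acute_of[[e]] + 1, sec(cp$secondary),
         adj(cp$cvd_death, rr("cvd_death")), acute_of[[e]] + 1)
  }
  P[8, 8] <- 1; P[9, 9] <- 1

  # per-state rewards (no SAEs in oracle configurations)
  u_base <- params$utilities$baseline[[sex]][1]
  um <- params$utilities$state_multiplier; ua <- params$utilities$acute_multiplier
  r_u <- c(u_base, u_base * ua$mi, u_base * um$mi, u_base * ua$stroke,
           u_base * um$stroke, u_base * ua$hf, u_base * um$hf, 0, 0)
  cc <- params$costs
  drug <- cc$annual_drug_cost[[strategy]]
  r_c <- c(drug,
           drug + cc$acute_event_cost$mi, drug + cc$chronic_annual_cost$mi,
           drug + cc$acute_event_cost$stroke,
           drug + cc$chronic_annual_cost$stroke,
           drug + cc$acute_event_cost$hf, drug + cc$chronic_annual_cost$hf,
           0, 0)
  r_ly <- c(rep(1, 7), 0, 0)

  t_max <- params$horizon_age_cap - age0 + 1
  pi_t <- c(1, rep(0, 8))
  d <- 1 / (1 + params$discount_rate)
  ly <- 0; qaly <- 0; cost <- 0
  for (t in 0:(t_max - 1)) {
    ly <- ly + sum(pi_t * r_ly)
    qaly <- qaly + d^t * sum(pi_t * r_u)
    cost <- cost + d^t * sum(pi_t * r_c)
    pi_t <- as.vector(pi_t %*% P)
  }
  list(ly = ly, qaly_disc = qaly, cost_disc = cost)
}
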