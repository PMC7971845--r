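# Payer-perspective economics: per-cycle cost and utility accrual,
# discounting, and purchasing-power-parity currency conversion. All
# monetary quantities are 2017 international dollars unless converted.

HEALTH_STATES <- c("well", "acute_mi", "post_mi", "acute_stroke",
                   "post_stroke", "acute_hf", "post_hf",
                   "cvd_death", "noncvd_death")

state_event_type <- function(state) {
  sub("^(acute|post)_", "", state)
}

#' Per-cycle cost
#'
#' Additive accrual for one model year: strategy-specific annual drug cost
#' (all alive cycles -- treatment continues after events), the acute
#' hospitalisation cost when the cycle is spent in an acute event state,
#' the chronic annual cost for post-event states, and the serious adverse
#' event cost in cycles where an SAE occurs. Death states accrue nothing
#' (the fatal transition ends accrual; event costs were accrued in the
#' acute cycle of the corresponding event).
#'
#' @param state Character vector of health states (see `HEALTH_STATES`).
#' @param sae Logical vector: SAE occurred this cycle.
#' @param strategy `"intensive"` or `"standard"`.
#' @param cp Cost parameter block (`params$costs`).
#' @return Numeric vector of costs (Int$).
#' @export
cycle_cost <- function(state, sae, strategy, cp) {
  if (any(unlist(cp) < 0)) stop("configured costs must be >= 0")
  drug <- cp$annual_drug_cost[[strategy]]
  n <- length(state)
  cost <- numeric(n)
  alive <- !state %in% c("cvd_death", "noncvd_death")
  cost[alive] <- drug
  acute <- grepl("^acute_", state)
  if (any(acute)) {
    ev <- state_event_type(state[acute])
    cost[acute] <- cost[acute] + unlist(cp$acute_event_cost)[ev]
  }
  post <- grepl("^post_", state)
  if (any(post)) {
    ev <- state_event_type(state[post])
    cost[post] <- cost[post] + unlist(cp$chronic_annual_cost)[ev]
  }
  cost[alive & sae] <- cost[alive & sae] + cp$sae_cost
  unname(cost)
}

#' Per-cycle utility weight
#'
#' Age-sex baseline utility (hypertensive population norms) multiplied by a
#' state-specific factor: 1 in the event-free state, an acute multiplier in
#' the year of an event, a chronic multiplier in post-event states. Cycles
#' with a serious adverse event spend one week at the SAE utility before
#' returning to the cycle's health state, giving the time-weighted average
#' `u - (u - u_sae) * (weeks * 7 / 365.25)`. Death states contribute 0.
#' Results are clamped to \[0, 1\].
#'
#' @param age Age during the cycle (vectorised).
#' @param sex `"male"`/`"female"`.
#' @param state Health state occupied during the cycle.
#' @param sae Logical: SAE during the cycle.
#' @param up Utility parameter block (`params$utilities`).
#' @return Numeric vector of utility weights in \[0, 1\].
#' @export
cycle_utility <- function(age, sex, state, sae, up) {
  n <- length(state)
  band <- findInterval(age, up$baseline$age_lo)
  band <- pmax(band, 1)
  base <- ifelse(sex == "female", up$baseline$female[band],
                 up$baseline$male[band])
  mult <- rep(1, n)
  acute <- grepl("^acute_", state)
  post <- grepl("^post_", state)
  if (any(acute))
    mult[acute] <- unlist(up$acute_multiplier)[state_event_type(state[acute])]
  if (any(post))
    mult[post] <- unlist(up$state_multiplier)[state_event_type(state[post])]
  u <- base * mult
  frac <- up$sae_duration_weeks * 7 / 365.25
  u <- ifelse(sae, u - (u - up$sae_utility_value) * frac, u)
  u[state %in% c("cvd_death", "noncvd_death")] <- 0
  unname(pmin(pmax(u, 0), 1))
}

#' Discount an amount to present value
#'
#' `amount / (1 + rate)^cycle_index`; cycle 0 is undiscounted.
#'
#' @param amount Amount (vectorised).
#' @param cycle_index Integer cycle index >= 0 (vectorised).
#' @param rate Annual discount rate (>= 0, default 0.03).
#' @return Present value.
#' @export
discount <- function(amount, cycle_index, rate = 0.03) {
  if (any(cycle_index < 0)) stop("cycle_index must be >= 0")
  if (rate < 0) stop("rate must be >= 0")
  amount / (1 + rate)^cycle_index
}

#' Convert international dollars to yuan at purchasing power parity
#'
#' @param int_dollars Amount in Int$.
#' @param ppp_rate Yuan per Int$ (default 3.54, the 2017 PPP rate).
#' @return Amount in yuan.
#' @export
ppp_convert <- function(int_dollars, ppp_rate = 3.54) {
  if (ppp_rate <= 0) stop("ppp_rate must be > 0")
  int_dollars * ppp_rate
}
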