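# Individual-level 9-state annual-cycle microsimulation. States: an
# event-free treated state, acute and chronic (post) states for each of
# myocardial infarction, stroke and heart failure, and two absorbing death
# states (CVD / non-CVD). Competing events within a cycle are resolved by a
# single categorical draw (rate-normalised if the probabilities sum past 1),
# serious adverse events are drawn independently (risk-neutral by
# assumption), and both treatment arms replay identical per-individual
# uniform streams (common random numbers), so a null treatment effect gives
# exactly zero deltas.
#
# Cycle convention (pinned by tests): the state labels the year being lived;
# a year accrues life-years, utility and cost if the individual is alive at
# its start; the transition draw at the end of the year decides the next
# year's state; a death draw ends accrual (death years accrue nothing).
# Acute states last exactly one cycle; the draw out of an acute state uses
# the elevated first-post-event-year probabilities (this is the
# multiple-events-in-the-first-year pathway: a secondary event may fire
# directly out of the acute year). No half-cycle correction.

STATE_WELL <- 1L
STATE_ACUTE <- c(mi = 2L, stroke = 4L, hf = 6L)
STATE_POST <- c(mi = 3L, stroke = 5L, hf = 7L)
STATE_CVD_DEATH <- 8L
STATE_NONCVD_DEATH <- 9L
EVENT_TYPES <- c("mi", "stroke", "hf")

#' Per-individual common-random-number streams
#'
#' Two uniform streams per individual (event draw, SAE draw), each cycle one
#' number, generated from a per-individual substream seed derived from
#' `(seed, individual index, run)`. Streams depend only on that triple, so
#' replaying them across treatment arms (common random numbers) or growing
#' the cohort leaves earlier individuals' draws unchanged.
#'
#' @param n Number of individuals.
#' @param t_max Maximum number of cycles.
#' @param seed Master seed (integer).
#' @param run Replicate / PSA-run index (default 0).
#' @return List of two `n x t_max` matrices: `event`, `sae`.
#' @export
crn_streams <- function(n, t_max, seed, run = 0) {
  U <- matrix(0, n, 2 * t_max)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  for (i in seq_len(n)) {
    s <- (as.double(seed) * 48271 + i * 1009 + run * 9973) %% 2147483647
    set.seed(as.integer(s))
    U[i, ] <- stats::runif(2 * t_max)
  }
  # interleaved layout: each cycle consumes (event, sae) in order, so the
  # first t cycles' draws do not depend on t_max (prefix consistency)
  list(event = U[, seq(1, 2 * t_max, by = 2), drop = FALSE],
       sae = U[, seq(2, 2 * t_max, by = 2), drop = FALSE])
}

#' Bootstrap individuals from an eligible population
#'
#' Draws `n` individuals with replacement, with sampling probability
#' proportional to `survey_weight`, so the simulated cohort preserves the
#' joint covariate structure of the weighted population.
#'
#' @param pop Non-empty population `data.frame`.
#' @param n Number of draws.
#' @param seed RNG seed.
#' @return `data.frame` of `n` sampled individuals.
#' @export
bootstrap_individuals <- function(pop, n, seed) {
  if (nrow(pop) == 0) stop("cannot bootstrap from an empty population")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  idx <- sample.int(nrow(pop), n, replace = TRUE, prob = pop$survey_weight)
  out <- pop[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-cycle transition probability matrix (columns: mi, stroke, hf,
# cvd_death, noncvd_death) for the subset of individuals given, at their
# current age, given their current state.
transition_probs <- function(df, state, age, strategy, params) {
  n <- length(state)
  P <- matrix(0, n, 5)
  rr <- function(what) rr_or_1(params, strategy, what)
  P[, 5] <- background_noncvd_prob(age, df$sex, params)

  well <- state == STATE_WELL
  if (any(well)) {
    dfw <- df[well, , drop = FALSE]
    dfw$age <- age[well]
    pe <- primary_event_probs(dfw, params)
    P[well, 1] <- apply_relative_risk(pe$mi, rr("mi"))
    P[well, 2] <- apply_relative_risk(pe$stroke, rr("stroke"))
    P[well, 3] <- apply_relative_risk(pe$hf, rr("hf"))
    P[well, 4] <- apply_relative_risk(params$p_cvd_death_well, rr("cvd_death"))
  }
  for (e in EVENT_TYPES) {
    for (first_year in c(TRUE, FALSE)) {
      i <- if (first_year) state == STATE_ACUTE[[e]] else state == STATE_POST[[e]]
      if (!any(i)) next
      cp <- params$chronic_probs[[e]]
      p_sec <- if (first_year) cp$secondary_y1 else cp$secondary
      p_die <- if (first_year) cp$cvd_death_y1 else cp$cvd_death
      for (k in seq_along(EVENT_TYPES)) {
        # a same-type recurrence within the acute year is not modelled as a
        # separate event (acute states last exactly one cycle); the further-
        # event pathway out of the acute year covers different event types
        if (first_year && EVENT_TYPES[k] == e) next
        mix <- params$secondary_mix[[EVENT_TYPES[k]]]
        P[i, k] <- apply_relative_risk(min(p_sec * mix, 1 - 1e-12),
                                       rr(EVENT_TYPES[k]))
      }
      P[i, 4] <- apply_relative_risk(p_die, rr("cvd_death"))
    }
  }
  P
}

# Core vectorised engine. `streams` from crn_streams() (or compatible).
# Returns per-individual totals; with trace = TRUE also per-cycle matrices.
simulate_cohort <- function(inds, strategy, params, streams, trace = FALSE) {
  n <- nrow(inds)
  cap <- params$horizon_age_cap
  age0 <- inds$age
  t_max <- max(cap - min(age0) + 1L, 1L)
  if (ncol(streams$event) < t_max)
    stop("streams cover ", ncol(streams$event), " cycles; ", t_max, " needed")
  r <- params$discount_rate
  p_sae <- apply_relative_risk(params$sae_prob_standard,
                               rr_or_1(params, strategy, "sae"))

  state <- rep(STATE_WELL, n)
  ly <- numeric(n); qaly <- numeric(n); qaly_d <- numeric(n)
  cost <- numeric(n); cost_d <- numeric(n); sae_n <- integer(n)
  nev <- matrix(0L, n, 3, dimnames = list(NULL, EVENT_TYPES))
  ev5 <- matrix(FALSE, n, 3, dimnames = list(NULL, EVENT_TYPES))
  death_cause <- integer(n)   # 0 alive, 1 cvd, 2 noncvd
  death_cycle <- rep(NA_integer_, n)
  surv <- numeric(0)
  warned_norm <- FALSE
  tr <- if (trace) list(state = matrix(NA_integer_, n, 0),
                        sae = matrix(NA, n, 0),
                        cost = matrix(NA_real_, n, 0),
                        utility = matrix(NA_real_, n, 0)) else NULL

  for (t in 0:(t_max - 1L)) {
    age_t <- age0 + t
    alive <- death_cause == 0L
    active <- alive & age_t <= cap
    surv <- c(surv, mean(alive))
    if (!any(active)) break

    # --- accrual for the year being lived ---
    st_chr <- HEALTH_STATES[state[active]]
    sae_t <- streams$sae[active, t + 1L] < p_sae
    u <- cycle_utility(age_t[active], inds$sex[active], st_chr, sae_t,
                       params$utilities)
    cst <- cycle_cost(st_chr, sae_t, strategy, params$costs)
    dfac <- 1 / (1 + r)^t
    ly[active] <- ly[active] + 1
    qaly[active] <- qaly[active] + u
    qaly_d[active] <- qaly_d[active] + u * dfac
    cost[active] <- cost[active] + cst
    cost_d[active] <- cost_d[active] + cst * dfac
    sae_n[active] <- sae_n[active] + sae_t
    if (trace) {
      pad <- function(m, v, default) {
        col <- rep(default, n); col[active] <- v; cbind(m, col)
      }
      tr$state <- cbind(tr$state, ifelse(alive, state, state))
      tr$sae <- pad(tr$sae, sae_t, NA)
      tr$cost <- pad(tr$cost, cst, NA_real_)
      tr$utility <- pad(tr$utility, u, NA_real_)
    }

    # --- end-of-year transition draw ---
    dfa <- inds[active, , drop = FALSE]
    P <- transition_probs(dfa, state[active], age_t[active], strategy, params)
    rs <- rowSums(P)
    over <- rs > 1
    if (any(over)) {
      if (!warned_norm) {
        warning("competing per-cycle probabilities exceeded 1 for ",
                sum(over), " individual-cycle(s); rate-normalised")
        warned_norm <- TRUE
      }
      P[over, ] <- P[over, ] / rs[over]
    }
    u_ev <- streams$event[active, t + 1L]
    cum <- P
    for (k in 2:5) cum[, k] <- cum[, k - 1] + P[, k]
    cat6 <- 1L + (u_ev >= cum[, 1]) + (u_ev >= cum[, 2]) +
      (u_ev >= cum[, 3]) + (u_ev >= cum[, 4]) + (u_ev >= cum[, 5])

    idx <- which(active)
    new_state <- state[idx]
    for (k in 1:3) {
      hit <- cat6 == k
      if (any(hit)) {
        new_state[hit] <- STATE_ACUTE[[k]]
        nev[idx[hit], k] <- nev[idx[hit], k] + 1L
        if (t < 5) ev5[idx[hit], k] <- TRUE
      }
    }
    died_cvd <- cat6 == 4L
    died_ncvd <- cat6 == 5L
    cont <- cat6 == 6L
    # continue: acute states mature into their post state, others persist
    mature <- cont & state[idx] %in% STATE_ACUTE
    new_state[mature] <- state[idx][mature] + 1L
    new_state[died_cvd] <- STATE_CVD_DEATH
    new_state[died_ncvd] <- STATE_NONCVD_DEATH
    state[idx] <- new_state
    death_cause[idx[died_cvd]] <- 1L
    death_cause[idx[died_ncvd]] <- 2L
    death_cycle[idx[died_cvd | died_ncvd]] <- t
  }

  res <- list(
    individual = data.frame(
      ly = ly, qaly = qaly, qaly_disc = qaly_d,
      cost = cost, cost_disc = cost_d, n_sae = sae_n,
      n_mi = nev[, "mi"], n_stroke = nev[, "stroke"], n_hf = nev[, "hf"],
      mi_5y = ev5[, "mi"], stroke_5y = ev5[, "stroke"], hf_5y = ev5[, "hf"],
      cvd_death_5y = death_cause == 1L & !is.na(death_cycle) & death_cycle < 5,
      death_5y = death_cause != 0L & !is.na(death_cycle) & death_cycle < 5,
      death_cause = c("alive_at_cap", "cvd_death",
                      "noncvd_death")[death_cause + 1L],
      death_cycle = death_cycle
    ),
    survival = surv
  )
  if (trace) res$trace <- tr
  res
}

#' Simulate one individual's trajectory
#'
#' Runs the microsimulation engine for a single individual and returns the
#' full per-cycle trajectory plus totals.
#'
#' @param ind One-row `data.frame` of covariates.
#' @param strategy `"intensive"` or `"standard"`.
#' @param params `model_params`.
#' @param seed Seed for the individual's uniform streams (ignored if
#'   `streams` given).
#' @param streams Optional pre-built streams (for common-random-number
#'   pairing across strategies).
#' @return List of class `trajectory`: `cycles` (`data.frame` with `cycle`,
#'   `age`, `state`, `sae`, `cost`, `utility`, `cost_disc`, `utility_disc`)
#'   and `totals` (`ly`, `qaly_disc`, `cost_disc`, undiscounted versions,
#'   event counts, `death_cause`, `death_cycle`).
#' @export
simulate_individual <- function(ind, strategy, params, seed = 1L,
                                streams = NULL) {
  ind <- as.data.frame(ind, stringsAsFactors = FALSE)
  stopifnot(nrow(ind) == 1)
  t_max <- max(params$horizon_age_cap - ind$age + 1L, 1L)
  if (is.null(streams)) streams <- crn_streams(1L, t_max, seed)
  res <- simulate_cohort(ind, strategy, params, streams, trace = TRUE)
  k <- ncol(res$trace$cost)
  lived <- !is.na(res$trace$cost[1, seq_len(k)])
  ncyc <- sum(lived)
  cyc <- data.frame(
    cycle = seq_len(ncyc) - 1L,
    age = ind$age + seq_len(ncyc) - 1L,
    state = HEALTH_STATES[res$trace$state[1, seq_len(ncyc)]],
    sae = res$trace$sae[1, seq_len(ncyc)],
    cost = res$trace$cost[1, seq_len(ncyc)],
    utility = res$trace$utility[1, seq_len(ncyc)]
  )
  cyc$cost_disc <- discount(cyc$cost, cyc$cycle, params$discount_rate)
  cyc$utility_disc <- discount(cyc$utility, cyc$cycle, params$discount_rate)
  tot <- as.list(res$individual[1, ])
  structure(list(cycles = cyc, totals = tot), class = "trajectory")
}

#' Run one treatment strategy over a cohort
#'
#' Simulates every individual through the model under one strategy and
#' aggregates to cohort level.
#'
#' @param cohort `data.frame` of (bootstrapped, eligible) individuals.
#' @param strategy `"intensive"` or `"standard"`.
#' @param params `model_params`.
#' @param seed Master seed for the per-individual streams.
#' @param streams Optional pre-built streams (overrides `seed`).
#' @param run Replicate index forwarded to [crn_streams()].
#' @return List of class `strategy_result`: `n`, `strategy`,
#'   `mean_cost_disc`, `mean_qaly_disc`, `mean_qaly`, `mean_ly`,
#'   `five_year` (named cumulative incidences for `mi`, `stroke`, `hf`,
#'   `cvd_death`, `all_death`), `lifetime_events` (mean counts),
#'   `survival` (per-cycle alive fraction), `individual` (per-individual
#'   totals), `baseline` (age/sex, for life-table validation).
#' @export
run_strategy <- function(cohort, strategy, params, seed = 1L,
                         streams = NULL, run = 0) {
  if (nrow(cohort) == 0) stop("cohort is empty")
  validate_model_params(params)
  t_max <- max(params$horizon_age_cap - min(cohort$age) + 1L, 1L)
  if (is.null(streams))
    streams <- crn_streams(nrow(cohort), t_max, seed, run = run)
  res <- simulate_cohort(cohort, strategy, params, streams)
  ind <- res$individual
  structure(list(
    n = nrow(cohort), strategy = strategy,
    mean_cost_disc = mean(ind$cost_disc),
    mean_cost = mean(ind$cost),
    mean_qaly_disc = mean(ind$qaly_disc),
    mean_qaly = mean(ind$qaly),
    mean_ly = mean(ind$ly),
    five_year = c(mi = mean(ind$mi_5y), stroke = mean(ind$stroke_5y),
                  hf = mean(ind$hf_5y), cvd_death = mean(ind$cvd_death_5y),
                  all_death = mean(ind$death_5y)),
    lifetime_events = c(mi = mean(ind$n_mi), stroke = mean(ind$n_stroke),
                        hf = mean(ind$n_hf), sae = mean(ind$n_sae)),
    survival = res$survival,
    individual = ind,
    baseline = data.frame(age = cohort$age, sex = cohort$sex)
  ), class = "strategy_result")
}

#' Compare intensive and standard strategies with common random numbers
#'
#' Simulates the same cohort under both strategies with identical
#' per-individual uniform streams, so every delta reflects parameters, not
#' sampling noise: with all treatment relative risks at 1 and equal arm
#' costs, every per-individual delta is exactly zero.
#'
#' @inheritParams run_strategy
#' @return List of class `strategy_comparison`: `intensive`, `standard`
#'   (both `strategy_result`), `deltas` (`data.frame` of per-individual
#'   `d_cost_disc`, `d_qaly_disc`, `d_ly`), and `summary` (mean deltas,
#'   5-year rate differences, point ICER).
#' @export
compare_strategies <- function(cohort, params, seed = 1L, run = 0) {
  if (nrow(cohort) == 0) stop("cohort is empty")
  t_max <- max(params$horizon_age_cap - min(cohort$age) + 1L, 1L)
  streams <- crn_streams(nrow(cohort), t_max, seed, run = run)
  si <- run_strategy(cohort, "intensive", params, streams = streams)
  ss <- run_strategy(cohort, "standard", params, streams = streams)
  deltas <- data.frame(
    d_cost_disc = si$individual$cost_disc - ss$individual$cost_disc,
    d_qaly_disc = si$individual$qaly_disc - ss$individual$qaly_disc,
    d_ly = si$individual$ly - ss$individual$ly
  )
  summ <- list(
    d_cost = mean(deltas$d_cost_disc),
    d_qaly = mean(deltas$d_qaly_disc),
    d_ly = mean(deltas$d_ly),
    d_five_year = ss$five_year - si$five_year,  # reduction (standard - intensive)
    icer = icer(mean(deltas$d_cost_disc), mean(deltas$d_qaly_disc))
  )
  structure(list(intensive = si, standard = ss, deltas = deltas,
                 summary = summ), class = "strategy_comparison")
}

#' Compare projected life expectancy with a life table
#'
#' Report-only validation: the cohort's mean simulated life-years versus the
#' whole-year life expectancy the life table implies for the same baseline
#' age/sex mix (same accrual convention, same age cap). Warns, but does not
#' fail, when the absolute difference exceeds `tolerance`.
#'
#' @param result A `strategy_result`.
#' @param life_table Life-table `data.frame` (`age`, `sex`, `qx`).
#' @param tolerance Warn threshold in years (default 1.5).
#' @param cap Age cap used by the simulation (default 100).
#' @return List `model_le`, `table_le`, `abs_difference`, `tolerance`,
#'   `within_tolerance`.
#' @export
validate_against_life_table <- function(result, life_table, tolerance = 1.5,
                                        cap = 100) {
  if (nrow(life_table) == 0) stop("empty life table")
  ages <- result$baseline$age
  if (min(life_table$age) > min(ages))
    stop("life table does not cover the cohort age range")
  table_le <- mean(life_table_expectancy(life_table, ages,
                                         result$baseline$sex, cap = cap))
  model_le <- result$mean_ly
  d <- abs(model_le - table_le)
  if (d > tolerance)
    warning(sprintf(
      "projected life expectancy deviates from the life table by %.2f years",
      d))
  list(model_le = model_le, table_le = table_le, abs_difference = d,
       tolerance = tolerance, within_tolerance = d <= tolerance)
}
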