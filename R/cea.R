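# Cost-effectiveness analytics over simulation output: ICER quadrant
# logic, national event scaling, one-way (tornado) sensitivity analysis,
# probabilistic sensitivity analysis, acceptability curves, and subgroup
# analyses.

#' Incremental cost-effectiveness ratio with quadrant handling
#'
#' Returns the ratio only where it is meaningful, otherwise a dominance
#' label: `"icer"` (more costly, more effective: north-east quadrant),
#' `"dominant"` (more effective, not more costly), `"dominated"` (less
#' effective, not less costly), `"southwest"` (cheaper and less effective:
#' ratio reported with an explicit quadrant tag), `"equivalence"` (both
#' deltas zero), `"undefined_ratio"` (zero QALY delta, nonzero cost delta).
#'
#' @param delta_cost Incremental cost (intervention minus comparator).
#' @param delta_qaly Incremental QALYs.
#' @return List `label`, `value` (Int$/QALY or `NA`), `delta_cost`,
#'   `delta_qaly`.
#' @export
icer <- function(delta_cost, delta_qaly) {
  if (!is.finite(delta_cost) || !is.finite(delta_qaly))
    stop("deltas must be finite")
  out <- list(label = NULL, value = NA_real_,
              delta_cost = delta_cost, delta_qaly = delta_qaly)
  if (delta_qaly == 0) {
    out$label <- if (delta_cost == 0) "equivalence" else "undefined_ratio"
  } else if (delta_qaly > 0) {
    if (delta_cost <= 0) out$label <- "dominant"
    else { out$label <- "icer"; out$value <- delta_cost / delta_qaly }
  } else {
    if (delta_cost >= 0) out$label <- "dominated"
    else { out$label <- "southwest"; out$value <- delta_cost / delta_qaly }
  }
  class(out) <- c("icer_result", "list")
  out
}

#' Scale a per-person rate difference to national event counts
#'
#' Multiplies a simulated per-person event-rate difference by the number of
#' eligible adults, giving events in millions when the eligible count is in
#' millions.
#'
#' @param rate_difference Per-person proportion (e.g. 5-year incidence-rate
#'   reduction).
#' @param eligible_millions Eligible population, millions (> 0).
#' @return Events in millions.
#' @export
scale_to_population <- function(rate_difference, eligible_millions) {
  if (any(eligible_millions <= 0)) stop("eligible_millions must be > 0")
  rate_difference * eligible_millions
}

#' One-way deterministic sensitivity analysis (tornado table)
#'
#' Re-evaluates the strategy comparison at the low and high end of each
#' parameter range, all else at base, with identical random streams for
#' every run (common random numbers), so a zero-width range reproduces the
#' base ICER exactly. Rows are sorted by the absolute ICER spread,
#' descending (tornado order).
#'
#' @param cohort Simulation cohort.
#' @param params `model_params`.
#' @param dsa_ranges Named list of `c(low, high)` keyed by `"a/b/c"`
#'   parameter paths; default `params$dsa`. Each range must contain the
#'   base value.
#' @param seed Master seed.
#' @return `data.frame` with `parameter`, `base_value`, `low`, `high`,
#'   `icer_low`, `icer_high`, `spread`; base-case ICER in attribute
#'   `base_icer`.
#' @export
one_way_sensitivity <- function(cohort, params, dsa_ranges = params$dsa,
                                seed = 1L) {
  for (nm in names(dsa_ranges)) {
    base <- param_get(params, nm)
    if (base < dsa_ranges[[nm]][1] || base > dsa_ranges[[nm]][2])
      stop("DSA range for '", nm, "' excludes the base value")
  }
  run_icer <- function(p) {
    cmp <- compare_strategies(cohort, p, seed = seed)
    v <- cmp$summary$icer
    if (is.na(v$value)) {
      # dominance has no finite ratio; sign it for ordering only
      if (v$label == "dominant") -Inf else Inf
    } else v$value
  }
  base_icer <- run_icer(params)
  rows <- lapply(names(dsa_ranges), function(nm) {
    rng <- dsa_ranges[[nm]]
    lo <- run_icer(param_set(params, nm, rng[1]))
    hi <- run_icer(param_set(params, nm, rng[2]))
    data.frame(parameter = nm, base_value = param_get(params, nm),
               low = rng[1], high = rng[2],
               icer_low = lo, icer_high = hi, spread = abs(hi - lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  out
}

# one parameter draw per PSA specification entry
sample_psa_params <- function(params, spec = params$psa) {
  drawn <- params
  for (e in spec) {
    base <- param_get(params, e$path)
    val <- switch(e$dist,
      gamma = {
        if (e$cv == 0 || base == 0) base else {
          shape <- 1 / e$cv^2
          stats::rgamma(1, shape = shape, rate = shape / base)
        }
      },
      beta = {
        if (e$cv == 0 || base == 0) base else {
          sd <- e$cv * base
          v <- sd^2
          if (v >= base * (1 - base)) stop(
            "beta variance too large for parameter ",
            paste(e$path, collapse = "/"))
          a <- base * (base * (1 - base) / v - 1)
          stats::rbeta(1, a, a * (1 - base) / base)
        }
      },
      lognormal = {
        if (e$sdlog == 0) base else
          stats::rlnorm(1, log(base) - e$sdlog^2 / 2, e$sdlog)
      },
      stop("unsupported PSA distribution family: ", e$dist)
    )
    drawn <- param_set(drawn, e$path, val)
  }
  drawn
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_runs` parameter sets from the support-matched distributions in
#' `params$psa` (Beta for probabilities/utilities, Gamma for costs,
#' log-normal for relative risks; mean-preserving), evaluates
#' [compare_strategies()] for each with run-specific but seed-derived
#' streams, and collects the incremental cost/QALY pairs. Reproducible
#' under a fixed seed.
#'
#' @param cohort Simulation cohort.
#' @param params `model_params`.
#' @param n_runs Number of probabilistic draws (default 1000).
#' @param seed Master seed.
#' @return `data.frame` of class `psa_samples`: `draw`, `d_cost`, `d_qaly`;
#'   sampled parameter values in attribute `sampled` (a list of named
#'   vectors).
#' @export
psa <- function(cohort, params, n_runs = 1000, seed = 1L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  d_cost <- numeric(n_runs); d_qaly <- numeric(n_runs)
  sampled <- vector("list", n_runs)
  for (k in seq_len(n_runs)) {
    set.seed(as.integer((as.double(seed) * 7919 + k) %% 2147483647))
    pk <- sample_psa_params(params)
    sampled[[k]] <- vapply(params$psa, function(e)
      param_get(pk, e$path), numeric(1))
    names(sampled[[k]]) <- vapply(params$psa, function(e)
      paste(e$path, collapse = "/"), character(1))
    cmp <- compare_strategies(cohort, pk, seed = seed, run = k)
    d_cost[k] <- cmp$summary$d_cost
    d_qaly[k] <- cmp$summary$d_qaly
  }
  out <- data.frame(draw = seq_len(n_runs), d_cost = d_cost, d_qaly = d_qaly)
  attr(out, "sampled") <- sampled
  class(out) <- c("psa_samples", "data.frame")
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the fraction of probabilistic
#' draws with positive net monetary benefit
#' (`lambda * dQALY - dCost > 0`).
#'
#' @param samples `psa_samples` (or any `data.frame` with `d_cost`,
#'   `d_qaly`).
#' @param thresholds Numeric vector of willingness-to-pay values
#'   (Int$/QALY).
#' @return `data.frame` `threshold`, `probability`.
#' @export
ceac <- function(samples, thresholds) {
  if (nrow(samples) == 0) stop("no PSA samples")
  prob <- vapply(thresholds, function(l)
    mean(l * samples$d_qaly - samples$d_cost > 0), numeric(1))
  data.frame(threshold = thresholds, probability = prob)
}

#' Willingness-to-pay thresholds
#'
#' The 1x GDP-per-capita threshold and its multiples (default 1x and 2x of
#' Int$16,782, China's 2017 GDP per capita).
#'
#' @param wtp_per_qaly Base threshold (default 16782).
#' @param multipliers Multipliers applied to it (default `c(1, 2)`).
#' @return Named numeric vector of thresholds.
#' @export
threshold_spec <- function(wtp_per_qaly = 16782, multipliers = c(1, 2)) {
  if (wtp_per_qaly <= 0 || any(multipliers <= 0))
    stop("thresholds must be positive")
  stats::setNames(wtp_per_qaly * multipliers,
                  paste0(multipliers, "x_gdp"))
}

#' Summarise a comparison into a cost-effectiveness result
#'
#' Combines the base-case comparison with probabilistic uncertainty:
#' percentile (2.5-97.5) intervals on the incremental cost and QALYs, the
#' point ICER with dominance handling, and the probability of
#' cost-effectiveness at each threshold (the ICER's uncertainty is reported
#' through these probabilities, not an ICER interval).
#'
#' @param comparison A `strategy_comparison`.
#' @param samples `psa_samples` for the same cohort/parameters.
#' @param thresholds Named thresholds, default [threshold_spec()].
#' @return List of class `cea_result`: per-arm mean cost/QALY, `d_cost` and
#'   `d_qaly` with `*_lo`/`*_hi` percentile bounds, `icer`
#'   (an `icer_result`), and `prob_ce` (named by threshold).
#' @export
cea_summary <- function(comparison, samples, thresholds = threshold_spec()) {
  qs <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  ci_c <- qs(samples$d_cost); ci_q <- qs(samples$d_qaly)
  cc <- ceac(samples, unname(thresholds))
  structure(list(
    cost_intensive = comparison$intensive$mean_cost_disc,
    cost_standard = comparison$standard$mean_cost_disc,
    qaly_intensive = comparison$intensive$mean_qaly_disc,
    qaly_standard = comparison$standard$mean_qaly_disc,
    d_cost = comparison$summary$d_cost, d_cost_lo = ci_c[1], d_cost_hi = ci_c[2],
    d_qaly = comparison$summary$d_qaly, d_qaly_lo = ci_q[1], d_qaly_hi = ci_q[2],
    icer = comparison$summary$icer,
    prob_ce = stats::setNames(cc$probability, names(thresholds))
  ), class = c("cea_result", "list"))
}

#' Default subgroup definitions
#'
#' Overall, by sex, by age band (< 75 / >= 75), and by baseline SBP band
#' (130-139 / >= 140), matching the usual reporting for intensive
#' blood-pressure control.
#'
#' @return Named list of predicate functions over a population
#'   `data.frame`.
#' @export
default_subgroups <- function() {
  list(
    overall = function(p) rep(TRUE, nrow(p)),
    male = function(p) p$sex == "male",
    female = function(p) p$sex == "female",
    age_lt_75 = function(p) p$age < 75,
    age_ge_75 = function(p) p$age >= 75,
    sbp_130_139 = function(p) p$sbp >= 130 & p$sbp < 140,
    sbp_ge_140 = function(p) p$sbp >= 140
  )
}

#' Subgroup cost-effectiveness analysis
#'
#' Runs the full pipeline (bootstrap from the subgroup, compare strategies,
#' probabilistic analysis, acceptability) independently within each
#' subgroup, with subgroup seeds derived from the master seed. Empty
#' subgroups are skipped with a warning.
#'
#' @param pop Eligible population `data.frame`.
#' @param params `model_params`.
#' @param subgroup_defs Named list of predicate functions, default
#'   [default_subgroups()].
#' @param seed Master seed.
#' @param n_boot Bootstrap replicates per subgroup.
#' @param n_psa Probabilistic draws per subgroup.
#' @param thresholds Named thresholds, default [threshold_spec()].
#' @return Named list of `cea_result` (skipped subgroups are `NULL`).
#' @export
subgroup_analysis <- function(pop, params, subgroup_defs = default_subgroups(),
                              seed = 1L, n_boot = 1000, n_psa = 200,
                              thresholds = threshold_spec()) {
  out <- vector("list", length(subgroup_defs))
  names(out) <- names(subgroup_defs)
  for (j in seq_along(subgroup_defs)) {
    keep <- subgroup_defs[[j]](pop)
    if (!any(keep)) {
      warning("subgroup '", names(subgroup_defs)[j], "' is empty; skipped")
      next
    }
    sub_seed <- as.integer((as.double(seed) * 131 + j * 104729) %% 2147483647)
    sub <- pop[keep, , drop = FALSE]
    cohort <- bootstrap_individuals(sub, n_boot, sub_seed)
    cmp <- compare_strategies(cohort, params, seed = sub_seed)
    sam <- psa(cohort, params, n_runs = n_psa, seed = sub_seed)
    out[[j]] <- cea_summary(cmp, sam, thresholds)
  }
  out
}
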