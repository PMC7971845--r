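# Synthetic survey-style populations: a Gaussian-copula generator with
# sex-stratified marginals emulating the joint covariate structure of a
# national ageing survey (age-SBP-treatment dependence, skewed positive
# survey weights), plus CSV input/output and survey-weighted estimation.

CONTINUOUS_VARS <- c("age", "sbp", "dbp", "total_chol", "hdl_chol", "creatinine")

POPULATION_COLUMNS <- c(
  "id", "age", "sex", "sbp", "dbp", "on_bp_treatment", "n_bp_med_classes",
  "smoker", "total_chol", "hdl_chol", "creatinine", "egfr",
  "hist_chd", "hist_stroke", "hist_hf", "diabetes", "esrd", "survey_weight"
)

# truncation bounds for the continuous marginals (field-plausible supports)
MARGINAL_BOUNDS <- list(
  age = c(45, 105), sbp = c(70, 250), dbp = c(40, 150),
  total_chol = c(80, 400), hdl_chol = c(15, 120), creatinine = c(0.3, 12)
)

#' Specification of a synthetic survey population
#'
#' Defines everything [generate_population()] needs: size, seed,
#' sex-stratified means/SDs for the continuous covariates, a rank-correlation
#' matrix among them (realised through a Gaussian copula), flag prevalences,
#' a logistic model linking age and SBP to antihypertensive treatment, and a
#' log-normal survey-weight model (weights are mean-normalised to 1 and then
#' scaled by `weight_scale`).
#'
#' @param n Number of individuals.
#' @param seed RNG seed; identical specs generate identical populations.
#' @param marginals Named list `male`/`female`, each with `mean` and `sd`
#'   named vectors over `age`, `sbp`, `dbp`, `total_chol`, `hdl_chol`,
#'   `creatinine`.
#' @param correlation Symmetric positive semi-definite rank-correlation
#'   matrix (unit diagonal) over the continuous covariates.
#' @param prevalence Named list `male`/`female` of flag prevalences for
#'   `smoker`, `diabetes`, `hist_chd`, `hist_stroke`, `hist_hf`, `esrd`.
#' @param treatment_model Logistic coefficients `intercept`, `age`
#'   (per year above 60), `sbp` (per mm Hg above 130) for being on
#'   antihypertensive treatment.
#' @param weight_model List `sdlog` (log-normal spread of raw weights).
#' @param weight_scale Persons represented per unit weight (e.g. set so that
#'   total weight equals a national population in millions).
#' @param p_male Probability an individual is male.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(n, seed = 1L,
                            marginals = default_marginals(),
                            correlation = default_correlation(),
                            prevalence = default_prevalence(),
                            treatment_model = list(intercept = -1.8,
                                                   age = 0.03, sbp = 0.025),
                            weight_model = list(sdlog = 0.5),
                            weight_scale = 1,
                            p_male = 0.47) {
  spec <- list(n = as.integer(n), seed = as.integer(seed),
               marginals = marginals, correlation = correlation,
               prevalence = prevalence, treatment_model = treatment_model,
               weight_model = weight_model, weight_scale = weight_scale,
               p_male = p_male)
  class(spec) <- c("population_spec", "list")
  validate_population_spec(spec)
  spec
}

#' @rdname population_spec
#' @export
default_marginals <- function() {
  list(
    male = list(
      mean = c(age = 59, sbp = 131, dbp = 79, total_chol = 182,
               hdl_chol = 49, creatinine = 0.92),
      sd = c(age = 10, sbp = 21, dbp = 12, total_chol = 36,
             hdl_chol = 12, creatinine = 0.24)
    ),
    female = list(
      mean = c(age = 59, sbp = 129, dbp = 77, total_chol = 192,
               hdl_chol = 53, creatinine = 0.74),
      sd = c(age = 10, sbp = 22, dbp = 12, total_chol = 38,
             hdl_chol = 13, creatinine = 0.20)
    )
  )
}

#' @rdname population_spec
#' @export
default_correlation <- function() {
  v <- CONTINUOUS_VARS
  R <- diag(length(v))
  dimnames(R) <- list(v, v)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_r("age", "sbp", 0.30)
  set_r("sbp", "dbp", 0.60)
  set_r("age", "dbp", 0.10)
  set_r("total_chol", "hdl_chol", 0.20)
  set_r("age", "creatinine", 0.15)
  R
}

#' @rdname population_spec
#' @export
default_prevalence <- function() {
  list(
    male = c(smoker = 0.52, diabetes = 0.12, hist_chd = 0.05,
             hist_stroke = 0.03, hist_hf = 0.010, esrd = 0.002),
    female = c(smoker = 0.04, diabetes = 0.13, hist_chd = 0.06,
               hist_stroke = 0.025, hist_hf = 0.012, esrd = 0.002)
  )
}

validate_population_spec <- function(spec) {
  if (spec$n < 0) stop("n must be >= 0")
  R <- spec$correlation
  if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-12))
    stop("correlation matrix must be symmetric with unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("correlation matrix must be positive semi-definite")
  for (s in c("male", "female")) {
    if (any(spec$marginals[[s]]$sd < 0))
      stop("marginal SDs must be >= 0")
    pv <- spec$prevalence[[s]]
    if (any(pv < 0 | pv > 1)) stop("prevalences must be in [0, 1]")
  }
  if (spec$weight_model$sdlog < 0) stop("weight sdlog must be >= 0")
  invisible(spec)
}

# truncated-normal quantile; degenerate SD collapses to the (clamped) mean
qtruncnorm <- function(p, mean, sd, lo, hi) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), length(p)))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + p * (phi - plo), mean, sd)
}

#' Generate a synthetic survey population
#'
#' Draws `spec$n` individuals. Continuous covariates are generated from a
#' Gaussian copula: a latent multivariate normal whose Pearson correlation is
#' chosen so the requested Spearman rank correlations are attained
#' (`2 sin(pi * rho_s / 6)`), pushed through truncated-normal marginal
#' quantile functions (monotone, so rank correlations are preserved
#' exactly in distribution). Binary flags are Bernoulli at the sex-specific
#' prevalences; treatment status follows the logistic model on realised age
#' and SBP, so the age-SBP-treatment dependence the eligibility screen needs
#' is present. eGFR is derived from creatinine via [estimate_egfr()]. Survey
#' weights are log-normal, mean-normalised to 1, times `weight_scale`.
#'
#' @param spec A [population_spec()].
#' @return `data.frame` with the documented population columns, one row per
#'   individual; deterministic given `spec` (including its seed).
#' @export
generate_population <- function(spec) {
  validate_population_spec(spec)
  n <- spec$n
  empty <- as.data.frame(
    stats::setNames(rep(list(logical(0)), length(POPULATION_COLUMNS)),
                    POPULATION_COLUMNS))
  if (n == 0) return(empty)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)

  sex <- ifelse(stats::runif(n) < spec$p_male, "male", "female")
  # latent Pearson correlation reproducing the requested rank correlation
  R <- 2 * sin(pi * spec$correlation / 6)
  diag(R) <- 1
  L <- chol_psd(R)
  Z <- matrix(stats::rnorm(n * length(CONTINUOUS_VARS)), n) %*% L
  U <- stats::pnorm(Z)
  colnames(U) <- CONTINUOUS_VARS

  X <- matrix(NA_real_, n, length(CONTINUOUS_VARS),
              dimnames = list(NULL, CONTINUOUS_VARS))
  for (s in c("male", "female")) {
    i <- which(sex == s)
    if (!length(i)) next
    m <- spec$marginals[[s]]
    for (v in CONTINUOUS_VARS) {
      b <- MARGINAL_BOUNDS[[v]]
      X[i, v] <- qtruncnorm(U[i, v], m$mean[[v]], m$sd[[v]], b[1], b[2])
    }
  }
  age <- as.integer(round(X[, "age"]))
  age <- pmin(pmax(age, 45L), 105L)
  hdl <- pmin(X[, "hdl_chol"], X[, "total_chol"] - 10)  # keep HDL < total

  flags <- matrix(NA, n, 6,
                  dimnames = list(NULL, c("smoker", "diabetes", "hist_chd",
                                          "hist_stroke", "hist_hf", "esrd")))
  for (s in c("male", "female")) {
    i <- which(sex == s)
    if (!length(i)) next
    pv <- spec$prevalence[[s]]
    for (f in colnames(flags))
      flags[i, f] <- stats::runif(length(i)) < pv[[f]]
  }

  tm <- spec$treatment_model
  p_treat <- stats::plogis(tm$intercept + tm$age * (age - 60) +
                             tm$sbp * (X[, "sbp"] - 130))
  on_trt <- stats::runif(n) < p_treat
  n_med <- integer(n)
  n_med[on_trt] <- sample(1:4, sum(on_trt), replace = TRUE,
                          prob = c(0.50, 0.30, 0.15, 0.05))

  w <- if (spec$weight_model$sdlog == 0) rep(1, n) else
    stats::rlnorm(n, 0, spec$weight_model$sdlog)
  w <- w / mean(w) * spec$weight_scale

  pop <- data.frame(
    id = sprintf("id%06d", seq_len(n)), age = age, sex = sex,
    sbp = X[, "sbp"], dbp = X[, "dbp"],
    on_bp_treatment = on_trt, n_bp_med_classes = n_med,
    smoker = flags[, "smoker"], total_chol = X[, "total_chol"],
    hdl_chol = hdl, creatinine = X[, "creatinine"],
    egfr = NA_real_,
    hist_chd = flags[, "hist_chd"], hist_stroke = flags[, "hist_stroke"],
    hist_hf = flags[, "hist_hf"], diabetes = flags[, "diabetes"],
    esrd = flags[, "esrd"], survey_weight = w,
    stringsAsFactors = FALSE
  )
  pop$egfr <- estimate_egfr(pop$creatinine, pop$age, pop$sex)
  rownames(pop) <- NULL
  pop
}

# Cholesky-like factor tolerant of semi-definite matrices
chol_psd <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  v <- pmax(e$values, 0)
  t(e$vectors %*% diag(sqrt(v), length(v)) %*% t(e$vectors))
}

#' Write / read a population CSV
#'
#' One row per person, UTF-8, `.` decimal separator, documented column
#' names. `read_population` accepts a `dialect` mapping (named character
#' vector or list, or a YAML file path: canonical name -> column name in the
#' file) for foreign files, drops rows with missing SBP (count attached as
#' attribute `n_dropped_missing_sbp`), and fails on non-numeric SBP values
#' naming the offending row.
#'
#' @param pop Population `data.frame`.
#' @param path CSV file path.
#' @param dialect Optional column mapping (canonical -> file column), or a
#'   YAML file containing one.
#' @return `read_population`: population `data.frame` with attribute
#'   `n_dropped_missing_sbp`.
#' @export
write_population <- function(pop, path) {
  utils::write.csv(pop, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path, dialect = NULL) {
  if (is.character(dialect) && length(dialect) == 1 && file.exists(dialect))
    dialect <- yaml::read_yaml(dialect)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (!is.null(dialect)) {
    dialect <- unlist(dialect)
    missing_src <- setdiff(unname(dialect), names(raw))
    if (length(missing_src))
      stop("mapped columns absent from file: ",
           paste(missing_src, collapse = ", "))
    names(raw)[match(unname(dialect), names(raw))] <- names(dialect)
  }
  required <- setdiff(POPULATION_COLUMNS, c("egfr", "creatinine",
                                            "n_bp_med_classes"))
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop("required columns missing: ", paste(miss, collapse = ", "))
  if (nrow(raw) == 0) {
    out <- raw
    attr(out, "n_dropped_missing_sbp") <- 0L
    return(out)
  }
  sbp_chr <- trimws(as.character(raw$sbp))
  is_missing <- is.na(raw$sbp) | sbp_chr == "" | toupper(sbp_chr) == "NA"
  sbp_num <- suppressWarnings(as.numeric(sbp_chr))
  bad <- which(!is_missing & is.na(sbp_num))
  if (length(bad))
    stop("non-numeric SBP value in row ", bad[1], ": '", sbp_chr[bad[1]], "'")
  dropped <- sum(is_missing)
  out <- raw[!is_missing, , drop = FALSE]
  out$sbp <- sbp_num[!is_missing]
  for (col in c("on_bp_treatment", "smoker", "hist_chd", "hist_stroke",
                "hist_hf", "diabetes", "esrd"))
    out[[col]] <- as.logical(out[[col]])
  if (any(out$survey_weight <= 0)) stop("survey weights must be > 0")
  if (is.null(out$egfr) && !is.null(out$creatinine))
    out$egfr <- estimate_egfr(out$creatinine, out$age, out$sex)
  rownames(out) <- NULL
  attr(out, "n_dropped_missing_sbp") <- as.integer(dropped)
  out
}

#' Survey-weighted proportion
#'
#' Ratio estimator `sum(w * y) / sum(w)` with a linearised variance
#' estimator `sum(w^2 (y - p)^2) / (sum w)^2` and a normal-approximation
#' (Wald) 95% confidence interval, plus the represented count
#' `sum(w * y)`. No finite-population or stratification corrections.
#'
#' @param pop Population `data.frame` with `survey_weight`.
#' @param indicator Logical vector of length `nrow(pop)`, or a function of
#'   the population returning one.
#' @return List `proportion`, `se`, `ci_low`, `ci_high`, `represented`.
#' @export
weighted_proportion <- function(pop, indicator) {
  if (nrow(pop) == 0) stop("cannot estimate a proportion on an empty population")
  y <- if (is.function(indicator)) indicator(pop) else indicator
  y <- as.numeric(y)
  if (length(y) != nrow(pop)) stop("indicator length must match population")
  w <- pop$survey_weight
  if (any(w <= 0)) stop("survey weights must be > 0")
  W <- sum(w)
  p <- sum(w * y) / W
  v <- sum(w^2 * (y - p)^2) / W^2
  se <- sqrt(v)
  z <- stats::qnorm(0.975)
  list(proportion = p, se = se,
       ci_low = max(0, p - z * se), ci_high = min(1, p + z * se),
       represented = sum(w * y))
}
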