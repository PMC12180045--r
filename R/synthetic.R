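#' Planted ground truth for synthetic data generation
#'
#' Bundles every parameter the generators use, so that a single object
#' (plus its seed) fully determines the generated tables and the values a
#' correct estimator should recover. Defaults emulate the study
#' conditions: adult stratum mean intakes in the vicinity of reported
#' global consumption levels (red/processed meat far above its 28 g/day
#' reference, saturated fats and added sugars well above their 3.8% and 5%
#' energy references), log-normal intake noise, an ecological log-burden
#' slope of -0.02 per score point, and individual-level odds/hazard ratios
#' of 0.863/0.85 per 10 score points, mirroring the scale of the
#' individual-level findings the analysis stages are meant to detect.
#'
#' @param seed Integer seed; recorded and re-used by every generator.
#' @param component_means Named planted mean intakes (gdd13 components; g/day
#'   at 2000 kcal/day for gram components, percent scale for percent-energy
#'   components).
#' @param intake_sigma Log-scale noise SD for intake draws.
#' @param eco_beta Planted coefficient of log burden on the score.
#' @param eco_sigma Gaussian noise SD on the log-burden scale.
#' @param outcome_logor Named planted log odds per 10 score points, one per
#'   binary outcome the participant generator plants.
#' @param hazard_loghr Planted log hazard per 10 score points.
#' @param cvd_death_fraction Fraction of deaths assigned a cause from the
#'   CVD test code set.
#' @return An object of class \code{"synthetic_truth"}.
#' @export
synthetic_truth <- function(seed = 1L,
                            component_means = NULL,
                            intake_sigma = 0.15,
                            eco_beta = -0.02,
                            eco_sigma = 0.10,
                            outcome_logor = c(ckm_stage34 = log(0.863)),
                            hazard_loghr = log(0.85),
                            cvd_death_fraction = 0.4) {
  if (is.null(component_means)) {
    component_means <- c(
      whole_grains = 120, whole_fruits = 130, nonstarchy_vegetables = 180,
      nuts_seeds = 12, legumes = 60, unsaturated_oils = 12,
      fish_shellfish = 35, starchy_vegetables = 150, dairy = 180,
      red_processed_meat = 70, eggs = 20,
      saturated_fats = 14.2, added_sugars = 12)
  }
  if (any(component_means < 0)) stop("planted means must be nonnegative")
  if (intake_sigma < 0 || eco_sigma < 0) stop("noise scales must be >= 0")
  structure(list(seed = as.integer(seed),
                 component_means = component_means,
                 intake_sigma = intake_sigma,
                 eco_beta = eco_beta, eco_sigma = eco_sigma,
                 outcome_logor = outcome_logor,
                 hazard_loghr = hazard_loghr,
                 cvd_death_fraction = cvd_death_fraction),
            class = "synthetic_truth")
}

percent_energy_components <- c("saturated_fats", "added_sugars")

#' Generate a stratified intake table
#'
#' Emulates the structure of a global stratum-level intake table: one
#' record per country x year x age group x sex x education x residence x
#' uncertainty draw. Intakes are drawn log-normally around the planted
#' stratum means (truncation at zero is automatic on that scale) with the
#' log-normal mean corrected so the draw expectation equals the planted
#' mean; a zero noise scale returns the planted means exactly. The energy
#' basis column follows the age-specific schedule.
#'
#' @param truth A \code{\link{synthetic_truth}}.
#' @param n_countries Number of synthetic countries.
#' @param years Numeric vector of survey years (non-empty).
#' @param n_draws Number of uncertainty draws per stratum (>= 2).
#' @param age_groups Age-group labels (bracket convention).
#' @return Stratum intake data frame passing
#'   \code{\link{read_stratum_table}} validation on round-trip.
#' @export
generate_stratum_intakes <- function(truth, n_countries = 2,
                                     years = c(2010, 2018), n_draws = 4,
                                     age_groups = c("1-2", "30-34",
                                                    "75-79")) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!length(years)) stop("years must be non-empty")
  if (n_draws < 2) stop("n_draws must be >= 2")
  set.seed(truth$seed)
  grid <- expand.grid(
    country = sprintf("C%02d", seq_len(n_countries)),
    year = as.integer(years), age_group = age_groups,
    sex = c("male", "female"), education = c("low", "medium", "high"),
    residence = c("urban", "rural"), draw = seq_len(n_draws),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$energy_basis <- energy_basis_for_age_group(grid$age_group)
  mns <- truth$component_means
  sig <- truth$intake_sigma
  for (comp in names(mns)) {
    m <- mns[[comp]]
    base <- if (comp %in% percent_energy_components) m
            else m * grid$energy_basis / 2000  # means planted on 2000 kcal
    grid[[comp]] <- if (sig == 0 || m == 0) base else
      stats::rlnorm(nrow(grid), meanlog = log(base) - sig^2 / 2,
                    sdlog = sig)
  }
  grid
}

#' Score a stratum intake table
#'
#' Standardizes each stratum record to the scoring basis and scores it,
#' returning per-record totals (and optionally per-component scores).
#'
#' @param tab Stratum intake table (generated or read).
#' @param config A \code{\link{scoring_config}}; its component names must
#'   all be intake columns of \code{tab}.
#' @param per_component Attach per-component score columns.
#' @return \code{tab} with added \code{phdi} column (and
#'   \code{score_<component>} columns if requested).
#' @export
score_stratum_table <- function(tab, config = phdi_config("gdd13"),
                                per_component = FALSE) {
  comps <- names(config$components)
  missing <- setdiff(comps, names(tab))
  if (length(missing))
    stop("table missing component column(s): ",
         paste(missing, collapse = ", "))
  units <- vapply(config$components, `[[`, "", "unit")
  target <- config$energy_basis_target
  scale <- target / tab$energy_basis
  totals <- numeric(nrow(tab))
  for (comp in comps) {
    x <- tab[[comp]]
    if (units[[comp]] == "grams_per_day") x <- x * scale
    s <- score_component(x, config$components[[comp]])
    if (per_component) tab[[paste0("score_", comp)]] <- s
    totals <- totals + s
  }
  tab$phdi <- totals
  tab
}

#' Generate a burden table from stratum scores
#'
#' Plants a log-linear ecological model: for each disease and measure,
#' \code{burden = exp(intercept + beta * score + year/age/sex effects +
#' noise)}, so values are strictly positive and the planted \code{beta} is
#' exactly recoverable by least squares on the log scale when the noise is
#' zero.
#'
#' @param truth A \code{\link{synthetic_truth}}.
#' @param phdi_by_stratum Data frame with columns year, age_group, sex,
#'   score (one row per stratum).
#' @param diseases Character vector of disease labels.
#' @return Burden data frame (disease, measure, year, age_group, sex,
#'   value).
#' @export
generate_burden_table <- function(truth, phdi_by_stratum,
                                  diseases = c("ischemic_heart_disease",
                                               "stroke", "diabetes",
                                               "chronic_kidney_disease")) {
  stopifnot(inherits(truth, "synthetic_truth"))
  need <- c("year", "age_group", "sex", "score")
  if (!all(need %in% names(phdi_by_stratum)))
    stop("phdi_by_stratum needs columns: ", paste(need, collapse = ", "))
  key <- unique(phdi_by_stratum[c("year", "age_group", "sex")])
  if (nrow(key) != nrow(phdi_by_stratum))
    stop("phdi_by_stratum strata (year, age_group, sex) must be unique")
  set.seed(truth$seed + 1L)
  measures <- c("incidence", "prevalence", "mortality", "dalys")
  ages <- sort(unique(phdi_by_stratum$age_group))
  rows <- list()
  for (d in seq_along(diseases)) for (m in seq_along(measures)) {
    s <- phdi_by_stratum
    eta <- (5 + 0.1 * d + 0.05 * m) +
      truth$eco_beta * s$score +
      0.002 * (s$year - 2000) +
      0.08 * (match(s$age_group, ages) - 1) +
      0.05 * (s$sex == "male") +
      (if (truth$eco_sigma > 0)
         stats::rnorm(nrow(s), 0, truth$eco_sigma) else 0)
    rows[[length(rows) + 1L]] <- data.frame(
      disease = diseases[d], measure = measures[m], year = s$year,
      age_group = s$age_group, sex = s$sex, value = exp(eta))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a participant cohort with planted effects
#'
#' Emulates the structure of a national examination-survey cohort: two
#' 24-hour dietary recalls drawn around the planted stratum means, a
#' diet-quality score computed from them, binary outcomes drawn from
#' planted logistic models in the score per 10 points (plus an age term),
#' exponential survival times with planted log hazard per 10 points,
#' administrative censoring, variable positive survey weights and a
#' two-PSU-per-stratum design, biomarkers, covariates and ICD-10 causes of
#' death with a stated fraction in the CVD test set (which deliberately
#' includes I63 to exercise the exclusion of cerebrovascular codes from
#' the heart-disease definition).
#'
#' @param truth A \code{\link{synthetic_truth}}.
#' @param n Number of participants (>= 1).
#' @param n_strata Number of design strata (2 PSUs each).
#' @param admin_censor_months Administrative censoring horizon.
#' @param config Scoring configuration used to compute the planted score.
#' @return Participant data frame; attribute \code{"truth"} carries the
#'   generating \code{synthetic_truth}.
#' @export
generate_participants <- function(truth, n = 1000, n_strata = 15,
                                  admin_censor_months = 240,
                                  config = phdi_config("gdd13")) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n < 1) stop("n must be >= 1")
  set.seed(truth$seed + 2L)
  stratum <- sample(sprintf("S%02d", seq_len(n_strata)), n, replace = TRUE)
  psu <- paste0(stratum, "-P", sample(1:2, n, replace = TRUE))
  dat <- data.frame(
    id = seq_len(n),
    cycle = sample(c("1999-2004", "2005-2012", "2013-2018"), n, TRUE),
    weight = stats::rlnorm(n, log(1), 0.4),
    stratum = stratum, psu = psu,
    age = stats::runif(n, 20, 80),
    sex = sample(c("male", "female"), n, TRUE),
    race_ethnicity = sample(c("nh_white", "other"), n, TRUE),
    education = sample(c("less_than_hs", "hs", "above_hs"), n, TRUE),
    marital = sample(c("married", "other"), n, TRUE),
    smoking = stats::rbinom(n, 1, 0.25),
    drinking = stats::rbinom(n, 1, 0.5),
    physical_activity = stats::rlnorm(n, log(20), 0.6),
    stringsAsFactors = FALSE)

  # two recalls around the adult planted means (2000 kcal basis)
  mns <- truth$component_means
  sig <- max(truth$intake_sigma, 1e-8)
  for (comp in names(mns)) {
    m <- max(mns[[comp]], 1e-6)
    for (r in 1:2)
      dat[[paste0("diet_", comp, "_", c("r1", "r2")[r])]] <-
        stats::rlnorm(n, log(m) - sig^2 / 2, sig)
  }
  diet_means <- sapply(names(mns), function(comp)
    (dat[[paste0("diet_", comp, "_r1")]] +
       dat[[paste0("diet_", comp, "_r2")]]) / 2)
  colnames(diet_means) <- names(mns)
  score_tab <- as.data.frame(diet_means)
  score_tab$energy_basis <- 2000
  dat$phdi <- score_stratum_table(score_tab, config)$phdi

  # biomarkers (marginals only; staging tests plant their own patterns)
  dat$bmi <- stats::rnorm(n, 27, 5)
  dat$waist <- 55 + 1.5 * dat$bmi + stats::rnorm(n, 0, 6)
  dat$sbp <- stats::rnorm(n, 122, 16)
  dat$dbp <- stats::rnorm(n, 74, 10)
  dat$bp_med <- stats::rbinom(n, 1, 0.15)
  dat$fasting_glucose <- stats::rlnorm(n, log(100), 0.15)
  dat$hba1c <- stats::rnorm(n, 5.6, 0.7)
  dat$dm_diagnosis <- stats::rbinom(n, 1, 0.08)
  dat$triglycerides <- stats::rlnorm(n, log(120), 0.4)
  dat$hdl <- stats::rnorm(n, 52, 13)
  dat$chol_ratio <- stats::rlnorm(n, log(3.8), 0.2)
  dat$dm <- dat$dm_diagnosis
  dat$egfr <- pmax(stats::rnorm(n, 95, 18), 5)
  dat$acr <- stats::rlnorm(n, log(10), 1)
  dat$heart_failure <- stats::rbinom(n, 1, 0.03)
  dat$coronary_artery_disease <- stats::rbinom(n, 1, 0.05)
  dat$heart_attack <- stats::rbinom(n, 1, 0.04)
  dat$stroke <- stats::rbinom(n, 1, 0.03)

  # planted binary outcomes: logit = alpha + logOR * phdi/10 + age term
  phdi10 <- dat$phdi / 10
  for (oc in names(truth$outcome_logor)) {
    eta <- -0.5 + truth$outcome_logor[[oc]] * phdi10 +
      0.01 * (dat$age - 50)
    dat[[oc]] <- stats::rbinom(n, 1, stats::plogis(eta))
  }

  # planted survival: exponential, log hazard linear in phdi/10
  rate <- exp(-5.5 + truth$hazard_loghr * phdi10 + 0.02 * (dat$age - 50))
  t_event <- stats::rexp(n, rate)
  dat$followup_months <- pmin(t_event, admin_censor_months)
  dat$vital_status <- as.integer(t_event <= admin_censor_months)
  cvd_codes <- c("I21", "I25", "I50", "I63")
  other_codes <- c("C34", "J44", "E14", "G30")
  is_cvd <- stats::runif(n) < truth$cvd_death_fraction
  dat$icd10_cause <- ifelse(dat$vital_status == 1,
    ifelse(is_cvd, sample(cvd_codes, n, TRUE), sample(other_codes, n, TRUE)),
    NA_character_)
  attr(dat, "truth") <- truth
  dat
}
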