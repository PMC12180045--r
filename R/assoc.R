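#' Survey design description
#'
#' Person-level sampling weights with stratum and primary-sampling-unit
#' (PSU) labels for design-based variance estimation. Every PSU must nest
#' in exactly one stratum and every stratum must contain at least two PSUs
#' so the between-PSU variance is estimable.
#'
#' @param data Participant data frame.
#' @param weight,stratum,psu Column names in \code{data}.
#' @return An object of class \code{"svy_design"} with elements
#'   \code{weight}, \code{stratum}, \code{psu} (vectors aligned with
#'   \code{data} rows).
#' @export
svy_design <- function(data, weight = "weight", stratum = "stratum",
                       psu = "psu") {
  for (cc in c(weight, stratum, psu))
    if (is.null(data[[cc]])) stop("design column not found: ", cc)
  w <- as.numeric(data[[weight]])
  if (any(is.na(w)) || any(w <= 0)) stop("weights must be positive")
  st <- as.character(data[[stratum]])
  ps <- as.character(data[[psu]])
  nest <- tapply(st, ps, function(s) length(unique(s)))
  if (any(nest > 1))
    stop("PSU(s) appearing in more than one stratum: ",
         paste(names(nest)[nest > 1], collapse = ", "))
  npsu <- tapply(ps, st, function(p) length(unique(p)))
  if (any(npsu < 2))
    stop("stratum(ta) with a single PSU (variance not estimable): ",
         paste(names(npsu)[npsu < 2], collapse = ", "))
  structure(list(weight = w, stratum = st, psu = ps), class = "svy_design")
}

#' Model specification for association analyses
#'
#' @param outcome Outcome column (binary for logistic models).
#' @param exposure Exposure column (default \code{"phdi"}).
#' @param scale Exposure units per reported contrast; the default 10 means
#'   odds/hazard ratios are reported per 10 score points.
#' @param covariates Adjustment covariates (default the standard
#'   individual-level set, \code{\link{default_covariates}}).
#' @return An object of class \code{"model_spec"}.
#' @export
model_spec <- function(outcome, exposure = "phdi", scale = 10,
                       covariates = default_covariates()) {
  if (!is.numeric(scale) || scale <= 0) stop("exposure scale must be > 0")
  structure(list(outcome = outcome, exposure = exposure,
                 scale = as.numeric(scale), covariates = covariates),
            class = "model_spec")
}

# Between-PSU linearized variance of a total, given per-observation score
# contributions (rows) and the design. Stratified with-replacement
# approximation: sum_h n_h/(n_h-1) * sum_j (z_hj - zbar_h)(z_hj - zbar_h)'
psu_variance <- function(scores, design) {
  scores <- as.matrix(scores)
  key <- paste(design$stratum, design$psu, sep = "\r")
  z <- rowsum(scores, key, reorder = FALSE)
  map <- tapply(design$stratum, key, `[`, 1)
  zstr <- as.character(map[rownames(z)])
  V <- matrix(0, ncol(scores), ncol(scores))
  for (h in unique(zstr)) {
    zh <- z[zstr == h, , drop = FALSE]
    nh <- nrow(zh)
    zc <- sweep(zh, 2, colMeans(zh))
    V <- V + nh / (nh - 1) * crossprod(zc)
  }
  V
}

design_df <- function(design) {
  length(unique(paste(design$stratum, design$psu, sep = "\r"))) -
    length(unique(design$stratum))
}

#' Survey-weighted logistic regression
#'
#' Weighted maximum-likelihood logistic fit (iteratively reweighted least
#' squares) with design-based variance by Taylor linearization: score
#' contributions are summed within PSUs and the stratified between-PSU
#' variance is sandwiched between inverse information matrices.
#' Confidence limits use a t reference with (number of PSUs - number of
#' strata) degrees of freedom. The association is reported as an odds
#' ratio per \code{spec$scale} points of the exposure.
#'
#' @param records Participant data frame (complete cases on the model
#'   variables are required; incomplete handling is upstream).
#' @param design A \code{\link{svy_design}} built on \code{records}.
#' @param spec A \code{\link{model_spec}} with a binary outcome.
#' @return List with \code{or}, \code{ci_low}, \code{ci_high},
#'   \code{log_or}, \code{se}, \code{p_value}, \code{n}, \code{events},
#'   \code{df}, and the underlying \code{fit}.
#' @export
weighted_logistic <- function(records, design, spec) {
  stopifnot(inherits(design, "svy_design"), inherits(spec, "model_spec"))
  y <- records[[spec$outcome]]
  if (is.null(y)) stop("outcome column not found: ", spec$outcome)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(y)) < 2L)
    stop("outcome has a single class; model not identifiable")
  covs <- intersect(spec$covariates, names(records))
  fml <- stats::reformulate(c(sprintf("I(%s/%g)", spec$exposure, spec$scale),
                              covs), response = spec$outcome)
  dat <- records
  dat$.w <- design$weight
  fit <- suppressWarnings(
    stats::glm(fml, family = stats::quasibinomial(), data = dat,
               weights = .w, control = stats::glm.control(maxit = 100)))
  if (!fit$converged) stop("logistic fit did not converge (separation?)")
  beta <- stats::coef(fit)
  if (anyNA(beta))
    stop("rank-deficient design; aliased term(s): ",
         paste(names(beta)[is.na(beta)], collapse = ", "))
  if (max(abs(beta[-1])) > 15)
    stop("diverging coefficient suggests separation; no estimate reported")
  X <- stats::model.matrix(fit)
  p <- stats::fitted(fit)
  w <- design$weight
  info <- crossprod(X, X * (w * p * (1 - p)))
  scores <- X * (w * (y - p))
  V <- solve(info, psu_variance(scores, design)) %*% solve(info)
  idx <- 2L  # exposure is the first non-intercept term
  se <- sqrt(V[idx, idx])
  est <- beta[[idx]]
  df <- design_df(design)
  tc <- stats::qt(0.975, df)
  list(or = exp(est), ci_low = exp(est - tc * se),
       ci_high = exp(est + tc * se), log_or = est, se = se,
       p_value = 2 * stats::pt(-abs(est / se), df),
       n = length(y), events = sum(y), df = df, fit = fit)
}

#' Survey-weighted proportional-hazards model
#'
#' Weighted Cox partial-likelihood fit (Efron tie handling) with robust
#' sandwich variance clustered on PSU, for all-cause or cardiovascular
#' mortality. The CVD filter classifies causes with
#' \code{\link{is_cvd_death}}; non-CVD deaths are treated as censored.
#' The association is reported as a hazard ratio per \code{spec$scale}
#' points of the exposure.
#'
#' @param records Participant data frame with columns
#'   \code{followup_months}, \code{vital_status} (1 = died) and, for the
#'   CVD filter, \code{icd10_cause}.
#' @param design A \code{\link{svy_design}} built on \code{records}.
#' @param spec A \code{\link{model_spec}} (outcome field unused here).
#' @param cause_filter \code{"all_cause"} or \code{"cvd"}.
#' @return List with \code{hr}, \code{ci_low}, \code{ci_high},
#'   \code{log_hr}, \code{se}, \code{p_value}, \code{n}, \code{events},
#'   and the underlying \code{fit}.
#' @export
weighted_cox <- function(records, design, spec,
                         cause_filter = c("all_cause", "cvd")) {
  stopifnot(inherits(design, "svy_design"), inherits(spec, "model_spec"))
  cause_filter <- match.arg(cause_filter)
  time <- as.numeric(records$followup_months)
  if (any(is.na(time)) || any(time <= 0))
    stop("follow-up times must be positive")
  dead <- as.numeric(records$vital_status) == 1
  event <- if (cause_filter == "all_cause") dead else {
    cause <- records$icd10_cause
    dead & !is.na(cause) & is_cvd_death(ifelse(is.na(cause), "I00", cause))
  }
  if (sum(event) == 0) stop("zero events after filtering")
  covs <- intersect(spec$covariates, names(records))
  dat <- records
  dat$.time <- time; dat$.event <- as.numeric(event)
  dat$.w <- design$weight; dat$.psu <- paste(design$stratum, design$psu)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(c(sprintf("I(%s/%g)", spec$exposure, spec$scale), covs),
          collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, weights = .w,
                         cluster = .psu, ties = "efron")
  est <- stats::coef(fit)[[1]]
  se <- sqrt(diag(fit$var))[1]  # robust variance when cluster is given
  df <- design_df(design)
  tc <- stats::qt(0.975, df)
  list(hr = exp(est), ci_low = exp(est - tc * se),
       ci_high = exp(est + tc * se), log_hr = est, se = se,
       p_value = 2 * stats::pt(-abs(est / se), df),
       n = nrow(records), events = sum(event), fit = fit)
}

#' Run a panel of outcome models
#'
#' Fits one association per requested outcome and assembles a forest-plot
#' style table with Bonferroni-adjusted p-values. Each outcome definition
#' is a list with fields:
#' \describe{
#'   \item{label}{row label;}
#'   \item{model}{\code{"logistic"} or \code{"cox"};}
#'   \item{outcome}{outcome column (logistic models);}
#'   \item{subset}{optional logical column restricting the eligible
#'     population (mortality models among participants with the disease);}
#'   \item{cause}{\code{"all_cause"} or \code{"cvd"} (cox models).}
#' }
#'
#' @param records Participant data frame.
#' @param outcomes List of outcome definitions (possibly empty).
#' @param spec_base A \code{\link{model_spec}} supplying exposure, scale
#'   and covariates.
#' @param family_size Bonferroni family size; defaults to the number of
#'   outcomes.
#' @param design_cols Named character vector locating weight/stratum/psu
#'   columns.
#' @return Data frame: outcome, model_type, eligible, estimate, ci_low,
#'   ci_high, p_value, p_adjusted, n, events.
#' @export
run_outcome_panel <- function(records, outcomes,
                              spec_base = model_spec("unused"),
                              family_size = NULL,
                              design_cols = c(weight = "weight",
                                              stratum = "stratum",
                                              psu = "psu")) {
  empty <- data.frame(outcome = character(0), model_type = character(0),
                      eligible = character(0), estimate = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      p_value = numeric(0), p_adjusted = numeric(0),
                      n = integer(0), events = integer(0))
  if (!length(outcomes)) return(empty)
  if (is.null(family_size)) family_size <- length(outcomes)
  rows <- lapply(outcomes, function(oc) {
    if (is.null(oc$label) || is.null(oc$model) ||
        !oc$model %in% c("logistic", "cox"))
      stop("outcome definition needs 'label' and model in ",
           "{'logistic', 'cox'}: ", oc$label %||% "<unnamed>")
    sub <- records
    eligible <- "all participants"
    if (!is.null(oc$subset)) {
      if (is.null(records[[oc$subset]]))
        stop("unknown subset column '", oc$subset, "' for outcome '",
             oc$label, "'")
      sub <- records[as.logical(records[[oc$subset]]) %in% TRUE, ]
      eligible <- paste("participants with", oc$subset)
    }
    des <- svy_design(sub, design_cols[["weight"]],
                      design_cols[["stratum"]], design_cols[["psu"]])
    if (oc$model == "logistic") {
      if (is.null(oc$outcome) || is.null(sub[[oc$outcome]]))
        stop("unknown outcome column for '", oc$label, "'")
      sp <- model_spec(oc$outcome, spec_base$exposure, spec_base$scale,
                       spec_base$covariates)
      ft <- weighted_logistic(sub, des, sp)
      est <- ft$or
    } else {
      ft <- weighted_cox(sub, des, spec_base,
                         cause_filter = oc$cause %||% "all_cause")
      est <- ft$hr
    }
    data.frame(outcome = oc$label, model_type = oc$model,
               eligible = eligible, estimate = est,
               ci_low = ft$ci_low, ci_high = ft$ci_high,
               p_value = ft$p_value,
               p_adjusted = bonferroni(ft$p_value, family_size),
               n = ft$n, events = ft$events)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
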