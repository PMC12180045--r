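#' Classify metabolic disorders for one participant
#'
#' Applies the configured cut-points to a participant's anthropometry and
#' laboratory values and returns one flag per disorder. A flag whose
#' required biomarker is missing is \code{NA} ("unknown"), never silently
#' \code{FALSE}. Diabetes and pre-diabetes are mutually exclusive;
#' metabolic syndrome requires at least 3 of its 5 criteria.
#'
#' @param record One-row data frame or named list with (any of) \code{bmi},
#'   \code{waist}, \code{sex}, \code{sbp}, \code{dbp}, \code{bp_med},
#'   \code{fasting_glucose}, \code{hba1c}, \code{dm_diagnosis},
#'   \code{triglycerides}, \code{hdl}.
#' @param config A \code{\link{study_config}} supplying the thresholds.
#' @return Named logical vector (may contain \code{NA}) with elements
#'   \code{overweight}, \code{abdominal_obesity}, \code{dm}, \code{pre_dm},
#'   \code{hypertension}, \code{hypertriglyceridemia},
#'   \code{metabolic_syndrome}.
#' @export
classify_metabolic <- function(record, config = study_config()) {
  th <- config$thresholds
  g <- function(f) { v <- record[[f]]; if (is.null(v) || length(v) != 1L) NA else v }
  male <- identical(tolower(as.character(g("sex"))), "male")
  num <- function(f) { v <- g(f); if (is.na(v)) NA_real_ else as.numeric(v) }
  flag <- function(f) { v <- g(f); if (is.na(v)) FALSE else isTRUE(as.logical(v)) }

  bmi <- num("bmi"); waist <- num("waist")
  sbp <- num("sbp"); dbp <- num("dbp")
  glu <- num("fasting_glucose"); a1c <- num("hba1c")
  tg <- num("triglycerides"); hdl <- num("hdl")

  overweight <- bmi >= th$overweight_bmi
  waist_cut <- if (male) th$waist_male else th$waist_female
  abdominal <- waist >= waist_cut
  dm <- (glu >= th$dm_glucose) | (a1c >= th$dm_hba1c) | flag("dm_diagnosis")
  dm <- if (flag("dm_diagnosis")) TRUE else dm
  pre_dm_raw <- (glu >= th$predm_glucose_low & glu <= th$predm_glucose_high) |
                (a1c >= th$predm_hba1c_low & a1c <= th$predm_hba1c_high)
  pre_dm <- if (isTRUE(dm)) FALSE else pre_dm_raw
  htn <- (sbp >= th$htn_sbp) | (dbp >= th$htn_dbp)
  htn <- if (flag("bp_med")) TRUE else htn
  htg <- tg >= th$hypertg

  # metabolic syndrome: >= 3 of waist, triglycerides, low HDL, BP, glucose
  hdl_cut <- if (male) th$mets_hdl_male else th$mets_hdl_female
  crit <- c(waist = abdominal,
            tg = tg >= th$hypertg,
            hdl = hdl < hdl_cut,
            bp = if (flag("bp_med")) TRUE else
                 (sbp >= th$mets_sbp) | (dbp >= th$mets_dbp),
            glucose = glu >= th$mets_glucose)
  mets <- if (sum(crit, na.rm = TRUE) >= 3L) TRUE
          else if (sum(is.na(crit)) + sum(crit, na.rm = TRUE) < 3L) FALSE
          else NA
  c(overweight = overweight, abdominal_obesity = abdominal, dm = dm,
    pre_dm = pre_dm, hypertension = htn, hypertriglyceridemia = htg,
    metabolic_syndrome = mets)
}

# KDIGO heat-map: 6 eGFR categories x 3 albuminuria categories, stored as
# data so it can be amended without touching code.
kdigo_matrix <- function() {
  m <- matrix(c(
    "low",       "moderate",  "high",       # G1
    "low",       "moderate",  "high",       # G2
    "moderate",  "high",      "very_high",  # G3a
    "high",      "very_high", "very_high",  # G3b
    "very_high", "very_high", "very_high",  # G4
    "very_high", "very_high", "very_high"   # G5
  ), nrow = 6, byrow = TRUE,
  dimnames = list(c("G1", "G2", "G3a", "G3b", "G4", "G5"),
                  c("A1", "A2", "A3")))
  m
}

#' KDIGO kidney-risk assessment
#'
#' Categorizes eGFR (mL/min/1.73m2) into G1-G5 (bands >= 90, 60-89, 45-59,
#' 30-44, 15-29, < 15) and the urinary albumin-to-creatinine ratio (mg/g)
#' into A1-A3 (< 30, 30-300, > 300), then looks up the composite risk in
#' the 18-cell KDIGO heat map.
#'
#' @param egfr Estimated glomerular filtration rate, > 0.
#' @param acr Albumin-to-creatinine ratio, >= 0.
#' @return List with \code{gfr_category}, \code{acr_category},
#'   \code{kdigo_risk} (one of low, moderate, high, very_high).
#' @examples
#' kdigo_risk(50, 400)  # G3a / A3, very_high
#' @export
kdigo_risk <- function(egfr, acr) {
  if (!is.numeric(egfr) || length(egfr) != 1L || is.na(egfr) || egfr <= 0)
    stop("egfr must be a single positive number")
  if (!is.numeric(acr) || length(acr) != 1L || is.na(acr) || acr < 0)
    stop("acr must be a single nonnegative number")
  gcat <- if (egfr >= 90) "G1" else if (egfr >= 60) "G2" else
          if (egfr >= 45) "G3a" else if (egfr >= 30) "G3b" else
          if (egfr >= 15) "G4" else "G5"
  acat <- if (acr < 30) "A1" else if (acr <= 300) "A2" else "A3"
  list(gfr_category = gcat, acr_category = acat,
       kdigo_risk = kdigo_matrix()[gcat, acat])
}

#' Assign a CKM syndrome stage
#'
#' Implements the staged cardiovascular-kidney-metabolic construct:
#' \itemize{
#'   \item stage 4 - clinical CVD (history of heart failure, coronary
#'     artery disease, heart attack or stroke), regardless of anything else;
#'   \item stage 3 - subclinical CVD: predicted 10-year CVD risk >= 20%
#'     or very-high KDIGO kidney risk;
#'   \item stage 2 - metabolic risk factors or CKD: diabetes, hypertension,
#'     hypertriglyceridemia, metabolic syndrome, or kidney disease
#'     (G3a or worse, or A2/A3 albuminuria);
#'   \item stage 1 - adiposity or pre-diabetes only;
#'   \item stage 0 - none of the above.
#' }
#' Unknown (\code{NA}) criteria that could raise the stage above what the
#' known criteria support make the stage indeterminate rather than guessed.
#'
#' @param flags Output of \code{\link{classify_metabolic}}.
#' @param kidney Output of \code{\link{kdigo_risk}}, or \code{NULL} if
#'   unavailable.
#' @param risk10y Predicted 10-year CVD risk in [0, 1], or \code{NA}.
#' @param clinical_cvd Named logical vector of history flags (any of
#'   \code{heart_failure}, \code{coronary_artery_disease},
#'   \code{heart_attack}, \code{stroke}), or a single logical.
#' @param config A \code{\link{study_config}}.
#' @return List with \code{stage} (integer 0-4 or \code{NA} if
#'   indeterminate) and \code{rationale} (character vector of triggered
#'   criteria; for indeterminate stages, the unknown inputs).
#' @export
assign_ckm_stage <- function(flags, kidney = NULL, risk10y = NA_real_,
                             clinical_cvd = FALSE, config = study_config()) {
  if (length(risk10y) != 1L || (!is.na(risk10y) &&
      (risk10y < 0 || risk10y > 1)))
    stop("risk10y must be a single value in [0, 1] or NA")
  cvd <- as.logical(clinical_cvd)
  if (is.null(names(cvd)) && length(cvd) == 1L) names(cvd) <- "clinical_cvd"
  if (any(cvd, na.rm = TRUE)) {
    return(list(stage = 4L,
                rationale = paste0("clinical CVD: ",
                                   paste(names(cvd)[which(cvd)],
                                         collapse = ", "))))
  }
  unknown <- character(0)
  if (any(is.na(cvd))) unknown <- c(unknown, "clinical_cvd")

  risk_thr <- config$thresholds$risk10y_subclinical
  s3_risk <- if (is.na(risk10y)) NA else risk10y >= risk_thr
  s3_kid <- if (is.null(kidney)) NA else
    identical(kidney$kdigo_risk, "very_high")
  s3 <- isTRUE(s3_risk) || isTRUE(s3_kid)
  if (s3) {
    r <- c(if (isTRUE(s3_risk)) sprintf("predicted 10-year CVD risk >= %g",
                                        risk_thr),
           if (isTRUE(s3_kid)) "very high KDIGO kidney risk")
    if (length(unknown))
      return(list(stage = NA_integer_,
                  rationale = c("indeterminate: unknown", unknown)))
    return(list(stage = 3L, rationale = r))
  }
  if (is.na(s3_risk)) unknown <- c(unknown, "risk10y")
  if (is.na(s3_kid)) unknown <- c(unknown, "kidney")

  ckd <- if (is.null(kidney)) NA else
    (!kidney$gfr_category %in% c("G1", "G2")) ||
    (kidney$acr_category %in% c("A2", "A3"))
  s2_flags <- flags[c("dm", "hypertension", "hypertriglyceridemia",
                      "metabolic_syndrome")]
  s2_all <- c(s2_flags, ckd = ckd)
  if (any(s2_all, na.rm = TRUE)) {
    if (length(unknown))
      return(list(stage = NA_integer_,
                  rationale = c("indeterminate: unknown", unknown)))
    return(list(stage = 2L, rationale = names(s2_all)[which(s2_all)]))
  }
  unknown <- c(unknown, names(s2_all)[is.na(s2_all)])

  s1_flags <- flags[c("overweight", "abdominal_obesity", "pre_dm")]
  if (any(s1_flags, na.rm = TRUE)) {
    if (length(unknown))
      return(list(stage = NA_integer_,
                  rationale = c("indeterminate: unknown", unknown)))
    return(list(stage = 1L, rationale = names(s1_flags)[which(s1_flags)]))
  }
  unknown <- c(unknown, names(s1_flags)[is.na(s1_flags)])
  if (length(unknown))
    return(list(stage = NA_integer_,
                rationale = c("indeterminate: unknown", unique(unknown))))
  list(stage = 0L, rationale = "no criteria met")
}

#' Logistic 10-year CVD risk model interface
#'
#' The 10-year risk is consumed through a pluggable logistic model:
#' \code{expit(intercept + sum(coefficients * inputs))}. The package does
#' not derive or ship the published PREVENT coefficients; users load real
#' coefficients from a file via \code{\link{read_risk_model}}, and a
#' documented synthetic test-double is available via
#' \code{risk_model_double()}.
#'
#' @param intercept Model intercept on the logit scale.
#' @param coefficients Named numeric vector; names are participant fields.
#' @return An object of class \code{"risk_model"}.
#' @export
risk_model <- function(intercept = 0, coefficients = numeric(0)) {
  if (length(coefficients) &&
      (is.null(names(coefficients)) || any(!nzchar(names(coefficients)))))
    stop("coefficients must be named by input field")
  structure(list(intercept = as.numeric(intercept),
                 coefficients = vapply(coefficients, as.numeric, 0)),
            class = "risk_model")
}

#' Synthetic logistic risk test-double
#'
#' A made-up logistic model over age, SBP, total/HDL cholesterol ratio,
#' diabetes and smoking, monotone in each risk factor. It is a stand-in
#' for exercising the staging pipeline, not a calibrated clinical model.
#' @return A \code{\link{risk_model}}.
#' @export
risk_model_double <- function() {
  risk_model(intercept = -7.5,
             coefficients = c(age = 0.065, sbp = 0.016,
                              chol_ratio = 0.20, dm = 0.55, smoking = 0.45))
}

#' Predict 10-year CVD risk
#'
#' @param record One-row data frame or named list holding every field the
#'   model's coefficients name.
#' @param model A \code{\link{risk_model}}.
#' @return Probability in [0, 1].
#' @export
predict_risk10y <- function(record, model) {
  stopifnot(inherits(model, "risk_model"))
  need <- names(model$coefficients)
  vals <- vapply(need, function(f) {
    v <- record[[f]]
    if (is.null(v) || length(v) != 1L || is.na(v)) NA_real_ else as.numeric(v)
  }, 0)
  if (any(is.na(vals)))
    stop("missing risk-model input(s): ",
         paste(need[is.na(vals)], collapse = ", "))
  eta <- model$intercept + sum(model$coefficients * vals)
  stats::plogis(eta)
}

#' Read / write a risk-model coefficient file
#'
#' Plain CSV with columns \code{term} and \code{estimate}; the row with
#' term \code{"(Intercept)"} is the intercept.
#'
#' @param path Path to a coefficient CSV.
#' @return A \code{\link{risk_model}}.
#' @export
read_risk_model <- function(path) {
  tab <- read_csv_strict(path)
  if (!all(c("term", "estimate") %in% names(tab)))
    stop("coefficient file needs columns 'term' and 'estimate'")
  est <- as.numeric(tab$estimate)
  ic <- tab$term == "(Intercept)"
  coefs <- est[!ic]; names(coefs) <- tab$term[!ic]
  risk_model(intercept = if (any(ic)) est[ic][1] else 0,
             coefficients = coefs)
}

#' @rdname read_risk_model
#' @param model A \code{\link{risk_model}} to serialize.
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  tab <- data.frame(term = c("(Intercept)", names(model$coefficients)),
                    estimate = c(model$intercept, model$coefficients))
  write_table(tab, path)
}

#' Classify a death as cardiovascular from its ICD-10 cause code
#'
#' CVD deaths are deaths from heart disease: root codes I00-I09, I11, I13
#' and I20-I51. Only the three-character root decides; any suffix after it
#' is ignored. Note I12 and the cerebrovascular chapter (I60-I69) are
#' deliberately outside the definition.
#'
#' @param icd10 Character vector of ICD-10 codes (e.g. \code{"I21.4"}).
#' @return Logical vector.
#' @examples
#' is_cvd_death(c("I21.4", "I12", "C34"))  # TRUE FALSE FALSE
#' @export
is_cvd_death <- function(icd10) {
  icd10 <- toupper(trimws(as.character(icd10)))
  ok <- grepl("^[A-Z][0-9]{2}(\\.?[0-9A-Z]*)?$", icd10)
  if (any(!ok))
    stop("unparseable ICD-10 code(s): ",
         paste(unique(icd10[!ok]), collapse = ", "))
  chapter <- substr(icd10, 1, 1)
  num <- as.integer(substr(icd10, 2, 3))
  chapter == "I" & ((num >= 0 & num <= 9) | num == 11 | num == 13 |
                    (num >= 20 & num <= 51))
}

#' Stage a participant table
#'
#' Convenience wrapper: runs metabolic classification, kidney assessment,
#' risk prediction and stage assignment over every row of a participant
#' table (as read by \code{\link{read_participant_table}}).
#'
#' @param records Participant data frame; clinical history flags are read
#'   from columns \code{heart_failure}, \code{coronary_artery_disease},
#'   \code{heart_attack}, \code{stroke} when present.
#' @param config A \code{\link{study_config}}.
#' @param model A \code{\link{risk_model}} for 10-year risk (default the
#'   synthetic test-double).
#' @return \code{records} with added columns \code{stage},
#'   \code{kdigo_risk}, \code{risk10y} and the metabolic flags.
#' @export
stage_participants <- function(records, config = study_config(),
                               model = risk_model_double()) {
  n <- nrow(records)
  hist_cols <- intersect(c("heart_failure", "coronary_artery_disease",
                           "heart_attack", "stroke"), names(records))
  out_stage <- integer(n); out_kr <- character(n); out_risk <- numeric(n)
  flag_mat <- matrix(NA, n, 7)
  for (i in seq_len(n)) {
    rec <- records[i, , drop = FALSE]
    flags <- classify_metabolic(rec, config)
    flag_mat[i, ] <- flags
    kid <- if (!is.na(rec$egfr %||% NA) && !is.na(rec$acr %||% NA))
      kdigo_risk(rec$egfr, rec$acr) else NULL
    risk <- tryCatch(predict_risk10y(rec, model),
                     error = function(e) NA_real_)
    cvd <- if (length(hist_cols))
      vapply(hist_cols, function(cc) isTRUE(as.logical(rec[[cc]])), TRUE)
      else FALSE
    st <- assign_ckm_stage(flags, kid, risk, cvd, config)
    out_stage[i] <- st$stage
    out_kr[i] <- if (is.null(kid)) NA_character_ else kid$kdigo_risk
    out_risk[i] <- risk
  }
  colnames(flag_mat) <- c("overweight", "abdominal_obesity", "dm", "pre_dm",
                          "hypertension", "hypertriglyceridemia",
                          "metabolic_syndrome")
  cbind(records, as.data.frame(flag_mat),
        data.frame(stage = out_stage, kdigo_risk = out_kr,
                   risk10y = out_risk))
}
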