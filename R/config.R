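#' Construct a food-group component specification
#'
#' A component spec describes one food group's piecewise-linear scoring
#' curve. Three kinds are supported:
#' \describe{
#'   \item{adequacy}{score rises linearly from 0 at zero intake to 10 at
#'     \code{optimal_low} and stays 10 for any higher intake.}
#'   \item{moderation}{score is 10 for intake at or below
#'     \code{optimal_high} and falls linearly to 0 at \code{max_ref}
#'     (unidirectional: zero intake keeps the maximum score).}
#'   \item{bidirectional}{score rises from 0 at zero intake to 10 at
#'     \code{optimal_low}, holds 10 on the optimal plateau, then falls to 0
#'     at \code{max_ref}. This is the modification that prevents zero
#'     intake of a moderation food from being scored as perfect adherence.}
#' }
#'
#' @param name Food-group label (unique within a configuration).
#' @param kind One of \code{"adequacy"}, \code{"moderation"},
#'   \code{"bidirectional"}.
#' @param unit \code{"grams_per_day"} (rescaled by energy standardization)
#'   or \code{"percent_energy"} (basis-invariant).
#' @param optimal_low Intake at which the score first reaches 10.
#' @param optimal_high Intake at which the score last holds 10; defaults to
#'   \code{optimal_low} (point optimum).
#' @param max_ref Intake at or above which the score is 0; required for
#'   moderation and bidirectional kinds.
#' @return An object of class \code{"component_spec"}.
#' @export
component_spec <- function(name, kind, unit = "grams_per_day",
                           optimal_low = 0, optimal_high = optimal_low,
                           max_ref = NA_real_) {
  kind <- match.arg(kind, c("adequacy", "moderation", "bidirectional"))
  unit <- match.arg(unit, c("grams_per_day", "percent_energy"))
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  optimal_low <- as.numeric(optimal_low)
  optimal_high <- as.numeric(optimal_high)
  max_ref <- as.numeric(max_ref)
  if (is.na(optimal_low) || is.na(optimal_high))
    stop("component '", name, "': optimal_low/optimal_high must be numeric")
  if (optimal_low < 0 || optimal_low > optimal_high)
    stop("component '", name,
         "': need 0 <= optimal_low <= optimal_high")
  if (kind %in% c("moderation", "bidirectional")) {
    if (is.na(max_ref))
      stop("component '", name, "': max_ref required for kind '", kind, "'")
    if (max_ref <= optimal_high)
      stop("component '", name, "': max_ref must exceed optimal_high")
  }
  structure(
    list(name = name, kind = kind, unit = unit,
         optimal_low = optimal_low, optimal_high = optimal_high,
         max_ref = max_ref,
         # score assigned at exactly zero intake, implied by the kind
         zero_floor = if (kind == "moderation") 10 else 0),
    class = "component_spec")
}

#' Construct a scoring configuration
#'
#' @param components List of \code{\link{component_spec}} objects.
#' @param energy_basis_target Energy basis (kcal/day) the scorer operates
#'   on; intakes are standardized to this basis before scoring. Default
#'   2500 kcal/day, the EAT-Lancet reference.
#' @param variant_name Label for the component set, e.g. \code{"full14"}.
#' @return An object of class \code{"scoring_config"}.
#' @export
scoring_config <- function(components, energy_basis_target = 2500,
                           variant_name = "custom") {
  if (!length(components) || !all(vapply(components, inherits, TRUE,
                                         "component_spec")))
    stop("components must be a non-empty list of component_spec objects")
  nms <- vapply(components, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop("duplicate component names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  if (!is.numeric(energy_basis_target) || energy_basis_target <= 0)
    stop("energy_basis_target must be > 0")
  names(components) <- nms
  structure(
    list(components = components,
         energy_basis_target = as.numeric(energy_basis_target),
         variant_name = variant_name),
    class = "scoring_config")
}

#' @export
print.scoring_config <- function(x, ...) {
  cat("PHDI scoring configuration '", x$variant_name, "': ",
      length(x$components), " components, basis ",
      x$energy_basis_target, " kcal/day, max total ",
      10L * length(x$components), "\n", sep = "")
  invisible(x)
}

# Default reference table. Optima follow the EAT-Lancet 2500 kcal/day
# reference diet; upper references use the published upper ranges where one
# exists, otherwise twice the plateau. Moderation components for saturated
# oils/trans fats and added sugars stay unidirectional; the remaining
# moderation-type groups are scored bidirectionally so that zero intake
# scores zero.
default_component_table <- function() {
  tab <- rbind(
    data.frame(name = "whole_grains",          kind = "adequacy",      unit = "grams_per_day",  optimal_low = 232, optimal_high = 232, max_ref = NA_real_),
    data.frame(name = "whole_fruits",          kind = "adequacy",      unit = "grams_per_day",  optimal_low = 200, optimal_high = 200, max_ref = NA_real_),
    data.frame(name = "nonstarchy_vegetables", kind = "adequacy",      unit = "grams_per_day",  optimal_low = 300, optimal_high = 300, max_ref = NA_real_),
    data.frame(name = "nuts_seeds",            kind = "adequacy",      unit = "grams_per_day",  optimal_low = 50,  optimal_high = 50,  max_ref = NA_real_),
    data.frame(name = "legumes",               kind = "adequacy",      unit = "grams_per_day",  optimal_low = 100, optimal_high = 100, max_ref = NA_real_),
    data.frame(name = "unsaturated_oils",      kind = "adequacy",      unit = "grams_per_day",  optimal_low = 40,  optimal_high = 40,  max_ref = NA_real_),
    data.frame(name = "fish_shellfish",        kind = "bidirectional", unit = "grams_per_day",  optimal_low = 28,  optimal_high = 28,  max_ref = 100),
    data.frame(name = "starchy_vegetables",    kind = "bidirectional", unit = "grams_per_day",  optimal_low = 50,  optimal_high = 50,  max_ref = 200),
    data.frame(name = "dairy",                 kind = "bidirectional", unit = "grams_per_day",  optimal_low = 250, optimal_high = 250, max_ref = 1000),
    data.frame(name = "red_processed_meat",    kind = "bidirectional", unit = "grams_per_day",  optimal_low = 14,  optimal_high = 14,  max_ref = 28),
    data.frame(name = "poultry",               kind = "bidirectional", unit = "grams_per_day",  optimal_low = 29,  optimal_high = 29,  max_ref = 58),
    data.frame(name = "eggs",                  kind = "bidirectional", unit = "grams_per_day",  optimal_low = 13,  optimal_high = 13,  max_ref = 26),
    data.frame(name = "saturated_fats",        kind = "moderation",    unit = "percent_energy", optimal_low = 0,   optimal_high = 0,   max_ref = 3.8),
    data.frame(name = "added_sugars",          kind = "moderation",    unit = "percent_energy", optimal_low = 0,   optimal_high = 0,   max_ref = 5)
  )
  rownames(tab) <- NULL
  tab
}

#' Built-in PHDI scoring configurations
#'
#' \code{"full14"} is the complete 14-component index (maximum total 140).
#' \code{"gdd13"} is the Global Dietary Database variant: poultry intake is
#' not reported there, so the component is dropped and the maximum total is
#' 130; nonsoy legumes and soy foods are scored as one combined group in
#' both variants.
#'
#' @param variant \code{"full14"} or \code{"gdd13"}.
#' @return A \code{\link{scoring_config}}.
#' @examples
#' phdi_config("gdd13")
#' @export
phdi_config <- function(variant = c("full14", "gdd13")) {
  variant <- match.arg(variant)
  tab <- default_component_table()
  if (variant == "gdd13") tab <- tab[tab$name != "poultry", ]
  comps <- lapply(seq_len(nrow(tab)), function(i)
    component_spec(tab$name[i], tab$kind[i], tab$unit[i],
                   tab$optimal_low[i], tab$optimal_high[i], tab$max_ref[i]))
  scoring_config(comps, energy_basis_target = 2500, variant_name = variant)
}

#' Load a scoring configuration from a YAML file
#'
#' The file must contain \code{variant_name}, \code{energy_basis_target}
#' and a \code{components} list; each component needs \code{name},
#' \code{kind}, \code{unit}, \code{optimal_low} and, where the kind
#' requires it, \code{max_ref}. See
#' \code{system.file("extdata", "phdi_full14.yaml", package = "planetdiet")}
#' for the shipped defaults.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated \code{\link{scoring_config}}.
#' @export
load_scoring_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("malformed config file '", path, "': ", conditionMessage(e)))
  for (key in c("components", "energy_basis_target"))
    if (is.null(doc[[key]]))
      stop("config file missing required key '", key, "'")
  comps <- lapply(doc$components, function(cm) {
    if (is.null(cm$name)) stop("component entry missing key 'name'")
    for (key in c("kind", "optimal_low"))
      if (is.null(cm[[key]]))
        stop("component '", cm$name, "' missing key '", key, "'")
    if (!cm$kind %in% c("adequacy", "moderation", "bidirectional"))
      stop("component '", cm$name, "': unknown kind '", cm$kind, "'")
    component_spec(cm$name, cm$kind,
                   unit = cm$unit %||% "grams_per_day",
                   optimal_low = cm$optimal_low,
                   optimal_high = cm$optimal_high %||% cm$optimal_low,
                   max_ref = cm$max_ref %||% NA_real_)
  })
  scoring_config(comps,
                 energy_basis_target = doc$energy_basis_target,
                 variant_name = doc$variant_name %||% "custom")
}

#' Write a scoring configuration to a YAML file
#'
#' @param config A \code{\link{scoring_config}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_scoring_config <- function(config, path) {
  stopifnot(inherits(config, "scoring_config"))
  doc <- list(
    variant_name = config$variant_name,
    energy_basis_target = config$energy_basis_target,
    components = lapply(unname(config$components), function(cm) {
      out <- list(name = cm$name, kind = cm$kind, unit = cm$unit,
                  optimal_low = cm$optimal_low,
                  optimal_high = cm$optimal_high)
      if (!is.na(cm$max_ref)) out$max_ref <- cm$max_ref
      out
    }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Study configuration for staging and association analysis
#'
#' Bundles the metabolic-disorder thresholds used by
#' \code{\link{classify_metabolic}}, the covariate list for the
#' individual-level models, the Bonferroni family size and the random seed.
#' All thresholds are overridable; the defaults follow the AHA CKM
#' advisory and standard US clinical cut-points.
#'
#' @param thresholds Named list of metabolic cut-points; see Details.
#' @param covariates Character vector of adjustment covariates.
#' @param family_size Number of tests in the Bonferroni family (>= 1).
#' @param seed Integer seed recorded in outputs.
#' @details Default thresholds: overweight BMI >= 25 kg/m2; abdominal
#'   obesity waist >= 102 cm (male) / 88 cm (female); diabetes fasting
#'   glucose >= 126 mg/dL or HbA1c >= 6.5% or diagnosis; pre-diabetes
#'   fasting glucose 100-125 mg/dL or HbA1c 5.7-6.4% without diabetes;
#'   hypertension SBP >= 130 or DBP >= 80 mmHg or medication;
#'   hypertriglyceridemia >= 150 mg/dL; metabolic syndrome >= 3 of the five
#'   ATP-III-style criteria (waist, triglycerides >= 150, HDL < 40/50
#'   mg/dL, BP >= 130/85 or medication, fasting glucose >= 100).
#' @return An object of class \code{"study_config"}.
#' @export
study_config <- function(thresholds = list(), covariates = default_covariates(),
                         family_size = 1L, seed = 1L) {
  def <- list(
    overweight_bmi = 25,
    waist_male = 102, waist_female = 88,
    dm_glucose = 126, dm_hba1c = 6.5,
    predm_glucose_low = 100, predm_glucose_high = 125,
    predm_hba1c_low = 5.7, predm_hba1c_high = 6.4,
    htn_sbp = 130, htn_dbp = 80,
    hypertg = 150,
    mets_hdl_male = 40, mets_hdl_female = 50,
    mets_sbp = 130, mets_dbp = 85, mets_glucose = 100,
    risk10y_subclinical = 0.20)
  unknown <- setdiff(names(thresholds), names(def))
  if (length(unknown))
    stop("unknown threshold name(s): ", paste(unknown, collapse = ", "))
  def[names(thresholds)] <- thresholds
  family_size <- as.integer(family_size)
  if (is.na(family_size) || family_size < 1L) stop("family_size must be >= 1")
  structure(list(thresholds = def, covariates = covariates,
                 family_size = family_size, seed = as.integer(seed)),
            class = "study_config")
}

#' Default individual-level adjustment covariates
#'
#' Survey cycle, age, sex, race/ethnicity, education, marital status,
#' smoking, drinking and physical activity (MET-hours/week, continuous).
#' @return Character vector of column names.
#' @export
default_covariates <- function() {
  c("cycle", "age", "sex", "race_ethnicity", "education", "marital",
    "smoking", "drinking", "physical_activity")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
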