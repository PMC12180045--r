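#' Intake profile for one stratum or person
#'
#' Holds per-component intakes with their units and the energy basis
#' (kcal/day) on which the intakes were reported. Gram-based intakes are
#' interpreted per day at that basis; percent-energy intakes are shares of
#' total energy and therefore basis-invariant.
#'
#' @param intakes Named numeric vector of intakes (all >= 0).
#' @param energy_basis Reporting energy basis in kcal/day (> 0).
#' @param units Named character vector (\code{"grams_per_day"} or
#'   \code{"percent_energy"}) aligned with \code{intakes}; defaults to
#'   grams for every component, or is taken from \code{config} if given.
#' @param config Optional \code{\link{scoring_config}} supplying the units.
#' @return An object of class \code{"intake_profile"}.
#' @export
intake_profile <- function(intakes, energy_basis, units = NULL, config = NULL) {
  if (is.null(names(intakes)) || any(!nzchar(names(intakes))))
    stop("intakes must be a fully named numeric vector")
  intakes <- vapply(intakes, as.numeric, 0)
  if (any(is.na(intakes)) || any(intakes < 0))
    stop("intakes must be nonnegative and non-missing")
  if (!is.numeric(energy_basis) || energy_basis <= 0)
    stop("energy_basis must be > 0")
  if (!is.null(config)) {
    stopifnot(inherits(config, "scoring_config"))
    units <- vapply(config$components, `[[`, "", "unit")
  }
  if (is.null(units)) {
    units <- rep("grams_per_day", length(intakes))
    names(units) <- names(intakes)
  }
  units <- units[names(intakes)]
  if (any(is.na(units)))
    stop("units missing for component(s): ",
         paste(names(intakes)[is.na(units)], collapse = ", "))
  pe <- intakes[units == "percent_energy"]
  if (length(pe) && any(pe > 100))
    stop("percent-energy intakes must lie in [0, 100]")
  structure(list(intakes = intakes, units = units,
                 energy_basis = as.numeric(energy_basis)),
            class = "intake_profile")
}

#' Standardize an intake profile to a target energy basis
#'
#' Gram-based intakes are multiplied by \code{target / energy_basis};
#' percent-energy intakes are unchanged. Scoring is defined on the
#' 2500 kcal/day EAT-Lancet basis, while stratified intake tables report on
#' age-specific bases (700-2000 kcal/day), so this rescaling is what makes
#' scores comparable across age groups.
#'
#' @param profile An \code{\link{intake_profile}}.
#' @param target Target energy basis in kcal/day (default 2500).
#' @return A new \code{intake_profile} with \code{energy_basis = target}.
#' @examples
#' p <- intake_profile(c(eggs = 9.04), energy_basis = 1000)
#' standardize_energy(p, 2500)$intakes  # 22.6 g/day
#' @export
standardize_energy <- function(profile, target = 2500) {
  stopifnot(inherits(profile, "intake_profile"))
  if (!is.numeric(target) || target <= 0) stop("target basis must be > 0")
  scale <- target / profile$energy_basis
  out <- profile
  grams <- out$units == "grams_per_day"
  out$intakes[grams] <- out$intakes[grams] * scale
  out$energy_basis <- as.numeric(target)
  out
}

#' Score a single food-group intake
#'
#' Evaluates the component's piecewise-linear proportional scoring curve at
#' the given intake (already on the scoring basis, in the spec's unit).
#' Vectorized over \code{intake}.
#'
#' @param intake Nonnegative intake value(s).
#' @param spec A \code{\link{component_spec}}.
#' @return Score(s) in [0, 10].
#' @examples
#' meat <- component_spec("red_processed_meat", "bidirectional",
#'                        optimal_low = 14, max_ref = 28)
#' score_component(c(0, 7, 14, 21, 28), meat)  # 0 5 10 5 0
#' @export
score_component <- function(intake, spec) {
  stopifnot(inherits(spec, "component_spec"))
  intake <- as.numeric(intake)
  if (any(is.na(intake)) || any(intake < 0))
    stop("intake must be nonnegative and non-missing")
  lo <- spec$optimal_low; hi <- spec$optimal_high; mx <- spec$max_ref
  rise <- function(x) if (lo > 0) 10 * pmin(x, lo) / lo else rep(10, length(x))
  fall <- function(x) 10 * pmax(0, pmin(1, (mx - x) / (mx - hi)))
  s <- switch(spec$kind,
    adequacy = rise(intake),
    moderation = ifelse(intake <= hi, 10, fall(intake)),
    bidirectional = ifelse(intake < lo, rise(intake),
                    ifelse(intake <= hi, 10, fall(intake))))
  pmin(10, pmax(0, s))
}

#' Score a full intake profile
#'
#' Applies \code{\link{score_component}} to every component in the
#' configuration and sums the per-component scores into the total index.
#' If the profile's energy basis differs from the configuration's scoring
#' basis it is standardized first via \code{\link{standardize_energy}}.
#'
#' @param profile An \code{\link{intake_profile}} covering every component
#'   of \code{config}.
#' @param config A \code{\link{scoring_config}}.
#' @return An object of class \code{"phdi_result"}: list with \code{total},
#'   named \code{per_component} scores and \code{variant_name}.
#' @export
score_profile <- function(profile, config) {
  stopifnot(inherits(profile, "intake_profile"),
            inherits(config, "scoring_config"))
  missing <- setdiff(names(config$components), names(profile$intakes))
  if (length(missing))
    stop("profile missing intake for component(s): ",
         paste(missing, collapse = ", "))
  mismatch <- names(config$components)[vapply(config$components, `[[`, "",
    "unit") != profile$units[names(config$components)]]
  if (length(mismatch))
    stop("unit mismatch for component(s): ", paste(mismatch, collapse = ", "))
  if (profile$energy_basis != config$energy_basis_target)
    profile <- standardize_energy(profile, config$energy_basis_target)
  per <- vapply(config$components, function(sp)
    score_component(profile$intakes[[sp$name]], sp), 0)
  structure(list(total = sum(per), per_component = per,
                 variant_name = config$variant_name),
            class = "phdi_result")
}

#' @export
print.phdi_result <- function(x, ...) {
  cat("PHDI (", x$variant_name, "): total ", format(x$total), " of ",
      10L * length(x$per_component), "\n", sep = "")
  print(round(x$per_component, 2))
  invisible(x)
}

#' Aggregate PHDI draws into a stratum summary
#'
#' Reduces per-draw (or per-stratum) total scores to a mean and a 95%
#' uncertainty interval taken as the 2.5th and 97.5th percentiles across
#' draws. Optional nonnegative weights give a weighted mean; the interval
#' remains the unweighted percentile span of the draws.
#'
#' @param draws Numeric vector of total scores, or a list of
#'   \code{phdi_result} objects.
#' @param weights Optional nonnegative weights, not all zero.
#' @param interval Logical; compute the uncertainty interval (requires at
#'   least two draws).
#' @return List with \code{mean}, \code{ui_low}, \code{ui_high},
#'   \code{n_draws}.
#' @export
aggregate_stratum <- function(draws, weights = NULL, interval = TRUE) {
  if (is.list(draws)) draws <- vapply(draws, `[[`, 0, "total")
  draws <- as.numeric(draws)
  if (!length(draws)) stop("no draws supplied")
  if (interval && length(draws) < 2L)
    stop("uncertainty interval requires at least 2 draws")
  if (is.null(weights)) {
    m <- mean(draws)
  } else {
    if (length(weights) != length(draws) || any(weights < 0) ||
        sum(weights) == 0)
      stop("weights must be nonnegative, same length as draws, not all zero")
    m <- sum(weights * draws) / sum(weights)
  }
  ui <- if (interval) unname(stats::quantile(draws, c(0.025, 0.975)))
        else c(NA_real_, NA_real_)
  list(mean = m, ui_low = ui[1], ui_high = ui[2], n_draws = length(draws))
}

#' Decompose a total-score difference into component contributions
#'
#' The contribution of component c to the difference in mean total score
#' between groups A and B is \code{mean_A(c) - mean_B(c)}; contributions
#' sum exactly to the total difference. This is how, e.g., a female-male
#' PHDI gap is attributed to individual food groups.
#'
#' @param group_a,group_b Named numeric vectors of mean per-component
#'   scores with identical component sets.
#' @return List with \code{contributions} (named, A minus B) and
#'   \code{total_difference}.
#' @export
decompose_difference <- function(group_a, group_b) {
  if (is.null(names(group_a)) || is.null(names(group_b)))
    stop("group means must be named by component")
  if (!setequal(names(group_a), names(group_b)) ||
      length(group_a) != length(group_b))
    stop("component sets differ between groups")
  diff <- group_a - group_b[names(group_a)]
  list(contributions = diff, total_difference = sum(diff))
}

#' Energy basis (kcal/day) for an age in years
#'
#' The age-specific reporting standards: 700 for ages 0 to <1, 1000 for
#' 1 to <2, 1300 for 2-5, 1700 for 6-10, 2000 for 11-74 and 1700 for 75+.
#'
#' @param age Age(s) in years (may be fractional).
#' @return Energy basis value(s) in kcal/day.
#' @export
energy_basis_for_age <- function(age) {
  age <- as.numeric(age)
  if (any(is.na(age)) || any(age < 0)) stop("age must be nonnegative")
  cuts <- c(0, 1, 2, 6, 11, 75, Inf)
  vals <- c(700, 1000, 1300, 1700, 2000, 1700)
  vals[findInterval(age, cuts, rightmost.closed = TRUE)]
}

#' Parse stratified-table age-group labels
#'
#' Accepts the bracket conventions used in global intake tables:
#' \code{"<1"} or \code{"0 to <1"}, ranges like \code{"1-2"}, \code{"30-34"}
#' (hyphen, en dash or \code{"a to b"} / \code{"a to <b"}), and open-ended
#' \code{"95+"}. Unparseable labels are errors, not guesses.
#'
#' @param label Character vector of age-group labels.
#' @return Data frame with columns \code{low}, \code{high} (years;
#'   \code{high} is \code{Inf} for open-ended groups) and \code{midpoint}.
#' @export
parse_age_group <- function(label) {
  one <- function(lab) {
    s <- gsub("–|—", "-", trimws(lab))
    if (grepl("^<\\s*([0-9.]+)$", s)) {
      hi <- as.numeric(sub("^<\\s*", "", s)); return(c(0, hi))
    }
    m <- regmatches(s, regexec("^([0-9.]+)\\s*(?:-|to)\\s*<?\\s*([0-9.]+)$", s))[[1]]
    if (length(m) == 3) return(as.numeric(m[2:3]))
    if (grepl("^([0-9.]+)\\s*\\+$", s))
      return(c(as.numeric(sub("\\+.*$", "", s)), Inf))
    stop("unparseable age-group label: '", lab, "'")
  }
  bounds <- t(vapply(label, one, c(0, 0)))
  low <- bounds[, 1]; high <- bounds[, 2]
  if (any(high <= low & is.finite(high)))
    stop("age-group upper bound must exceed lower bound")
  mid <- ifelse(is.finite(high), (low + high) / 2, low)
  data.frame(label = label, low = low, high = high, midpoint = mid,
             row.names = NULL)
}

#' Energy basis for an age-group label
#'
#' Pure function of the label: the bracket is parsed and the age-specific
#' basis looked up at the bracket midpoint (lower bound for open-ended
#' groups), which resolves brackets straddling two standards.
#'
#' @param label Character vector of age-group labels.
#' @return Energy basis value(s) in kcal/day.
#' @examples
#' energy_basis_for_age_group(c("0 to <1", "30-34", "95+"))
#' @export
energy_basis_for_age_group <- function(label) {
  energy_basis_for_age(parse_age_group(label)$midpoint)
}
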