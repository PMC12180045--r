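#' Linear time trend in a score series
#'
#' Ordinary least squares of mean score on calendar year, with a two-sided
#' test of zero slope. This is the "P for trend" used to decide whether a
#' subgroup's diet-quality score changed over the study window; the window
#' is whatever years the caller supplies.
#'
#' @param years Numeric vector of calendar years (>= 3 distinct values).
#' @param scores Mean scores aligned with \code{years}.
#' @return List with \code{slope} (score points per year), \code{p_value},
#'   \code{n_years}.
#' @export
linear_trend <- function(years, scores) {
  if (length(years) != length(scores))
    stop("years and scores must have equal length")
  if (length(unique(years)) < 3L)
    stop("trend test requires at least 3 distinct years")
  fit <- stats::lm(scores ~ years)
  # exact (noiseless) series are legitimate input; summary.lm warns on them
  sm <- suppressWarnings(summary(fit))$coefficients
  p <- if (nrow(sm) < 2 || is.na(sm["years", "Std. Error"]) ||
           sm["years", "Std. Error"] == 0) {
    # noiseless exact fit: slope determined, null decisively rejected
    # unless the slope is itself zero
    if (abs(stats::coef(fit)[["years"]]) < 1e-12) 1 else 0
  } else sm["years", "Pr(>|t|)"]
  list(slope = unname(stats::coef(fit)[["years"]]), p_value = p,
       n_years = length(unique(years)))
}

#' Sociodemographic index
#'
#' Geometric mean of the rescaled lag-distributed income, average years of
#' schooling, and fertility indices. All three must already be rescaled to
#' [0, 1] by the caller (the rescaling anchors are a property of the source
#' data, not of this function).
#'
#' @param income_index,schooling_index,fertility_index Values in [0, 1]
#'   (vectorized).
#' @return SDI in [0, 1].
#' @examples
#' sdi(0.25, 1, 1)  # 0.62996...
#' @export
sdi <- function(income_index, schooling_index, fertility_index) {
  v <- cbind(income_index, schooling_index, fertility_index)
  if (any(is.na(v)) || any(v < 0) || any(v > 1))
    stop("all three indices must lie in [0, 1]")
  (income_index * schooling_index * fertility_index)^(1 / 3)
}

#' Restricted cubic spline basis
#'
#' Natural (restricted) cubic spline basis in the truncated-power form:
#' with k knots the basis has k-1 columns (the linear term plus k-2
#' restricted cubic terms, each scaled by the squared overall knot span),
#' and any fitted curve is linear beyond the boundary knots. Used for the
#' dose-response of diet-quality score on the sociodemographic index with
#' 3 knots.
#'
#' @param x Numeric vector (>= 3 distinct values when knots are derived).
#' @param n_knots Number of knots when \code{knots} is NULL (default 3,
#'   placed at the 10th/50th/90th percentiles; more knots use evenly
#'   spaced probability points over the same span).
#' @param knots Optional strictly increasing knot locations (>= 3).
#' @return Matrix with \code{length(x)} rows and \code{k - 1} columns and
#'   attribute \code{"knots"}.
#' @export
rcs_basis <- function(x, n_knots = 3, knots = NULL) {
  x <- as.numeric(x)
  if (is.null(knots)) {
    if (length(unique(x)) < 3L) stop("need at least 3 distinct x values")
    probs <- if (n_knots == 3) c(0.10, 0.50, 0.90)
             else seq(0.05, 0.95, length.out = n_knots)
    knots <- unname(stats::quantile(x, probs, type = 7))
  }
  knots <- as.numeric(knots)
  k <- length(knots)
  if (k < 3L) stop("need at least 3 knots")
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing")
  tk <- knots[k]; tk1 <- knots[k - 1L]
  span2 <- (knots[k] - knots[1])^2
  pos3 <- function(u) pmax(u, 0)^3
  cols <- lapply(seq_len(k - 2L), function(j) {
    tj <- knots[j]
    (pos3(x - tj) -
       pos3(x - tk1) * (tk - tj) / (tk - tk1) +
       pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / span2
  })
  basis <- cbind(x, do.call(cbind, cols))
  colnames(basis) <- c("linear", if (k > 2)
    paste0("nonlin", seq_len(k - 2L)))
  attr(basis, "knots") <- knots
  basis
}

#' Ecological regression of disease burden on diet-quality score
#'
#' For each disease x measure cell, regresses (by default log-transformed)
#' burden on the stratum-level score with adjustment for year (continuous)
#' and age group and sex (categorical), by ordinary least squares. Returns
#' one association per cell with a Bonferroni-adjusted p-value using the
#' number of diseases as the family size. Being an ecological analysis, the
#' coefficients describe population strata, not individuals.
#'
#' @param burden Burden data frame (see \code{\link{read_burden_table}}):
#'   columns disease, measure, year, age_group, sex, value.
#' @param phdi Data frame with columns year, age_group, sex, score.
#' @param adjust Character subset of \code{c("year", "age", "sex")}.
#' @param log_transform Log-transform burden before fitting (default TRUE;
#'   recorded in the output).
#' @param family_size Bonferroni family size; defaults to the number of
#'   distinct diseases.
#' @return Data frame with one row per disease x measure: coefficient (per
#'   1 score point), ci_low, ci_high, p_value, p_adjusted, n, transform.
#' @export
ecological_regression <- function(burden, phdi,
                                  adjust = c("year", "age", "sex"),
                                  log_transform = TRUE,
                                  family_size = NULL) {
  adjust <- match.arg(adjust, several.ok = TRUE)
  need <- c("year", "age_group", "sex", "score")
  if (!all(need %in% names(phdi)))
    stop("phdi table needs columns: ", paste(need, collapse = ", "))
  dat <- merge(burden, phdi, by = c("year", "age_group", "sex"))
  if (!nrow(dat)) stop("stratum keys of burden and phdi tables do not align")
  if (is.null(family_size)) family_size <- length(unique(dat$disease))
  cells <- unique(dat[c("disease", "measure")])
  rhs <- c("score",
           if ("year" %in% adjust) "year",
           if ("age" %in% adjust) "factor(age_group)",
           if ("sex" %in% adjust) "factor(sex)")
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- dat[dat$disease == cells$disease[i] &
               dat$measure == cells$measure[i], ]
    if (nrow(sub) < 10L)
      stop("fewer than 10 joined rows for ", cells$disease[i], " / ",
           cells$measure[i])
    sub$.y <- if (log_transform) log(sub$value) else sub$value
    if (log_transform && any(!is.finite(sub$.y)))
      stop("log transform undefined for zero burden values; set ",
           "log_transform = FALSE or filter zeros")
    # drop adjustment factors with a single level in this cell
    keep <- vapply(rhs, function(tm) {
      v <- switch(tm, "factor(age_group)" = sub$age_group,
                  "factor(sex)" = sub$sex, sub$year)
      tm == "score" || length(unique(v)) > 1L
    }, TRUE)
    fml <- stats::reformulate(rhs[keep], response = ".y")
    fit <- stats::lm(fml, data = sub)
    if (anyNA(stats::coef(fit)))
      stop("rank-deficient design; aliased term(s): ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                 collapse = ", "))
    est <- stats::coef(fit)[["score"]]
    se <- suppressWarnings(summary(fit))$coefficients["score", "Std. Error"]
    df <- fit$df.residual
    p <- 2 * stats::pt(-abs(est / se), df)
    tcrit <- stats::qt(0.975, df)
    data.frame(disease = cells$disease[i], measure = cells$measure[i],
               coefficient = est, ci_low = est - tcrit * se,
               ci_high = est + tcrit * se, p_value = p,
               p_adjusted = bonferroni(p, family_size),
               n = nrow(sub),
               transform = if (log_transform) "log" else "identity")
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Bonferroni adjustment
#'
#' @param p P-value(s).
#' @param family_size Number of tests in the family (>= 1).
#' @return \code{min(1, p * family_size)}, elementwise.
#' @export
bonferroni <- function(p, family_size) {
  if (family_size < 1) stop("family_size must be >= 1")
  pmin(1, p * family_size)
}

#' Rank countries by mean score
#'
#' Descending by score; exact ties are broken lexicographically by country
#' label and flagged.
#'
#' @param scores Named numeric vector, country -> mean score.
#' @return Data frame with columns country, score, rank, tied.
#' @export
rank_countries <- function(scores) {
  if (!length(scores) || is.null(names(scores)))
    stop("scores must be a non-empty named vector")
  ord <- order(-scores, names(scores))
  out <- data.frame(country = names(scores)[ord],
                    score = unname(scores[ord]),
                    rank = seq_along(scores))
  out$tied <- duplicated(out$score) | duplicated(out$score, fromLast = TRUE)
  out
}
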