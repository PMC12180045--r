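# Shared fixtures and independent oracles.

# Dense-grid piecewise-linear oracle, built directly from a spec's
# breakpoints with stats::approx -- independent of score_component's
# arithmetic.
grid_score_oracle <- function(spec, intake) {
  lo <- spec$optimal_low; hi <- spec$optimal_high; mx <- spec$max_ref
  if (spec$kind == "adequacy") {
    xs <- if (lo > 0) c(0, lo) else c(0, 1)
    ys <- if (lo > 0) c(0, 10) else c(10, 10)
    right <- 10
  } else if (spec$kind == "moderation") {
    xs <- c(0, hi, mx); ys <- c(10, 10, 0); right <- 0
  } else {
    xs <- c(0, lo, hi, mx)
    ys <- c(if (lo > 0) 0 else 10, 10, 10, 0)
    right <- 0
  }
  keep <- !duplicated(xs)
  stats::approx(xs[keep], ys[keep], xout = intake, yleft = ys[1],
                yright = right, ties = "ordered")$y
}

random_component_spec <- function() {
  kind <- sample(c("adequacy", "moderation", "bidirectional"), 1)
  lo <- runif(1, 0, 200)
  hi <- lo + sample(c(0, runif(1, 0, 50)), 1)
  if (kind == "moderation") { lo <- 0; hi <- runif(1, 0, 100) }
  mx <- hi + runif(1, 0.5, 150)
  component_spec("x", kind,
                 optimal_low = lo, optimal_high = hi,
                 max_ref = if (kind == "adequacy") NA_real_ else mx)
}

# Exhaustive brute-force stage oracle over discrete criteria: a record is
# summarized by logical criteria; stage is the max rule triggered.
stage_oracle <- function(cvd, risk_ge20, kdigo_very_high, s2_any, s1_any) {
  if (cvd) 4L
  else if (risk_ge20 || kdigo_very_high) 3L
  else if (s2_any) 2L
  else if (s1_any) 1L
  else 0L
}

# Closed-form OLS via normal equations, independent of lm().
ols_oracle <- function(X, y) solve(crossprod(X), crossprod(X, y))

make_flags <- function(overweight = FALSE, abdominal_obesity = FALSE,
                       dm = FALSE, pre_dm = FALSE, hypertension = FALSE,
                       hypertriglyceridemia = FALSE,
                       metabolic_syndrome = FALSE) {
  c(overweight = overweight, abdominal_obesity = abdominal_obesity,
    dm = dm, pre_dm = pre_dm, hypertension = hypertension,
    hypertriglyceridemia = hypertriglyceridemia,
    metabolic_syndrome = metabolic_syndrome)
}

optimal_profile <- function(config) {
  opt <- vapply(config$components, `[[`, 0, "optimal_low")
  intake_profile(opt, config$energy_basis_target, config = config)
}
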