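healthy <- list(sex = "male", bmi = 23, waist = 85, sbp = 115, dbp = 70,
                bp_med = FALSE, fasting_glucose = 90, hba1c = 5.2,
                dm_diagnosis = FALSE, triglycerides = 100, hdl = 55)

test_that("metabolic flags follow the configured thresholds", {
  f <- classify_metabolic(healthy)
  expect_true(all(!f))

  f <- classify_metabolic(modifyList(healthy, list(bmi = 27)))
  expect_true(f[["overweight"]])
  expect_true(all(!f[setdiff(names(f), "overweight")]))

  f <- classify_metabolic(modifyList(healthy, list(fasting_glucose = 110)))
  expect_true(f[["pre_dm"]]); expect_false(f[["dm"]])
  f <- classify_metabolic(modifyList(healthy, list(fasting_glucose = 126)))
  expect_true(f[["dm"]]); expect_false(f[["pre_dm"]])  # mutually exclusive
  f <- classify_metabolic(modifyList(healthy,
                                     list(fasting_glucose = 110,
                                          dm_diagnosis = TRUE)))
  expect_true(f[["dm"]]); expect_false(f[["pre_dm"]])

  f <- classify_metabolic(modifyList(healthy, list(sbp = 131)))
  expect_true(f[["hypertension"]])
  f <- classify_metabolic(modifyList(healthy, list(bp_med = TRUE)))
  expect_true(f[["hypertension"]])

  # sex-specific waist cut: 95 cm flags a female but not a male
  f_m <- classify_metabolic(modifyList(healthy, list(waist = 95)))
  f_f <- classify_metabolic(modifyList(healthy,
                                       list(waist = 95, sex = "female")))
  expect_false(f_m[["abdominal_obesity"]])
  expect_true(f_f[["abdominal_obesity"]])

  # metabolic syndrome needs >= 3 of 5 criteria
  two <- modifyList(healthy, list(triglycerides = 180, hdl = 35))
  expect_false(classify_metabolic(two)[["metabolic_syndrome"]])
  three <- modifyList(two, list(fasting_glucose = 105))
  expect_true(classify_metabolic(three)[["metabolic_syndrome"]])

  # missing biomarker -> unknown flag, not FALSE
  f <- classify_metabolic(modifyList(healthy, list(bmi = NULL)))
  expect_true(is.na(f[["overweight"]]))
})

test_that("KDIGO lookup matches the declared 18-cell grid at boundaries", {
  expected <- list(
    G1  = c(A1 = "low", A2 = "moderate", A3 = "high"),
    G2  = c(A1 = "low", A2 = "moderate", A3 = "high"),
    G3a = c(A1 = "moderate", A2 = "high", A3 = "very_high"),
    G3b = c(A1 = "high", A2 = "very_high", A3 = "very_high"),
    G4  = c(A1 = "very_high", A2 = "very_high", A3 = "very_high"),
    G5  = c(A1 = "very_high", A2 = "very_high", A3 = "very_high"))
  egfr_probe <- list(G1 = c(90, 95, 200), G2 = c(60, 75, 89.999),
                     G3a = c(45, 50, 59.999), G3b = c(30, 40, 44.999),
                     G4 = c(15, 20, 29.999), G5 = c(0.1, 12, 14.999))
  acr_probe <- list(A1 = c(0, 29.999), A2 = c(30, 300), A3 = c(300.001, 5000))
  for (g in names(expected)) for (a in names(acr_probe))
    for (e in egfr_probe[[g]]) for (v in acr_probe[[a]]) {
      k <- kdigo_risk(e, v)
      expect_identical(k$gfr_category, g)
      expect_identical(k$acr_category, a)
      expect_identical(k$kdigo_risk, unname(expected[[g]][[a]]))
    }
  expect_error(kdigo_risk(-1, 10), "positive")
  expect_error(kdigo_risk(90, -1), "nonnegative")
})

test_that("stage assignment matches the brute-force criterion lattice", {
  # enumerate the full discrete lattice of stage-relevant criteria
  risks <- c("low", "moderate", "high", "very_high")
  grid <- expand.grid(cvd = c(FALSE, TRUE), risk10y = c(0.05, 0.25),
                      kdigo = risks, ckd = c(FALSE, TRUE),
                      dm = c(FALSE, TRUE), htn = c(FALSE, TRUE),
                      mets = c(FALSE, TRUE), over = c(FALSE, TRUE),
                      predm = c(FALSE, TRUE), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    kidney <- list(gfr_category = if (g$ckd) "G3a" else "G1",
                   acr_category = "A1", kdigo_risk = g$kdigo)
    flags <- make_flags(overweight = g$over, dm = g$dm,
                        hypertension = g$htn, metabolic_syndrome = g$mets,
                        pre_dm = g$predm && !g$dm)
    st <- assign_ckm_stage(flags, kidney, g$risk10y, g$cvd)
    want <- stage_oracle(g$cvd, g$risk10y >= 0.20,
                         g$kdigo == "very_high",
                         g$dm || g$htn || g$mets || g$ckd,
                         g$over || (g$predm && !g$dm))
    expect_identical(st$stage, want)
    if (want > 0L) expect_true(length(st$rationale) > 0)
  }
})

test_that("stage assignment is monotone and clinically dominated", {
  # adding criteria never lowers the stage
  set.seed(9)
  risks <- c("low", "moderate", "high", "very_high")
  for (i in 1:200) {
    base_flags <- make_flags(overweight = runif(1) < .5, dm = runif(1) < .5,
                             hypertension = runif(1) < .5,
                             pre_dm = runif(1) < .5)
    base_flags["pre_dm"] <- base_flags[["pre_dm"]] && !base_flags[["dm"]]
    kr <- sample(risks, 1)
    kidney <- list(gfr_category = "G2", acr_category = "A1",
                   kdigo_risk = kr)
    r <- runif(1)
    s0 <- assign_ckm_stage(base_flags, kidney, r, FALSE)$stage
    # raise one input
    up_flags <- base_flags; up_flags["metabolic_syndrome"] <- TRUE
    expect_gte(assign_ckm_stage(up_flags, kidney, r, FALSE)$stage, s0)
    kid_up <- kidney; kid_up$kdigo_risk <- "very_high"
    expect_gte(assign_ckm_stage(base_flags, kid_up, r, FALSE)$stage, s0)
    expect_gte(assign_ckm_stage(base_flags, kidney, min(1, r + 0.5),
                                FALSE)$stage, s0)
    # clinical CVD dominates everything
    expect_identical(assign_ckm_stage(base_flags, kidney, r,
                                      c(stroke = TRUE))$stage, 4L)
  }
})

test_that("stage examples and indeterminate propagation behave as defined", {
  none <- make_flags()
  kid_low <- list(gfr_category = "G1", acr_category = "A1",
                  kdigo_risk = "low")
  expect_identical(assign_ckm_stage(none, kid_low, 0.05, FALSE)$stage, 0L)
  expect_identical(assign_ckm_stage(none, kid_low, 0.25, FALSE)$stage, 3L)
  expect_identical(assign_ckm_stage(none, kid_low, 0.05,
                                    c(stroke = TRUE))$stage, 4L)
  # unknown risk with nothing else decisive -> indeterminate, not guessed
  st <- assign_ckm_stage(none, kid_low, NA, FALSE)
  expect_true(is.na(st$stage))
  expect_match(st$rationale[1], "indeterminate")
  # but unknown lower-tier inputs cannot mask clinical CVD
  expect_identical(assign_ckm_stage(none, NULL, NA,
                                    c(heart_attack = TRUE))$stage, 4L)
  expect_error(assign_ckm_stage(none, kid_low, 1.7, FALSE), "risk10y")
})

test_that("risk model interface is logistic, monotone, and file-stable", {
  expect_equal(predict_risk10y(list(), risk_model(0)), 0.5)
  m <- risk_model(-2, c(sbp = 0.02))
  expect_equal(predict_risk10y(list(sbp = 100), m), plogis(0))
  # monotone in sbp
  risks <- vapply(seq(90, 200, 10), function(s)
    predict_risk10y(list(sbp = s), m), 0)
  expect_true(all(diff(risks) >= 0))
  expect_error(predict_risk10y(list(), m), "sbp")

  dbl <- risk_model_double()
  rec <- list(age = 60, sbp = 140, chol_ratio = 4, dm = 1, smoking = 0)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_risk_model(dbl, tmp)
  expect_equal(predict_risk10y(rec, read_risk_model(tmp)),
               predict_risk10y(rec, dbl))
})

test_that("ICD-10 heart-disease classification is decided by the code root", {
  expect_true(is_cvd_death("I21.4"))
  expect_false(is_cvd_death("I12"))
  expect_false(is_cvd_death("C34"))
  # exhaustive over the whole circulatory chapter
  roots <- sprintf("I%02d", 0:99)
  inside <- c(0:9, 11, 13, 20:51)
  expect_equal(is_cvd_death(roots), as.integer(substr(roots, 2, 3)) %in% inside)
  # suffixes never change the result
  expect_equal(is_cvd_death(paste0(roots, ".9")), is_cvd_death(roots))
  expect_error(is_cvd_death("heart attack"), "unparseable")
})

test_that("participant staging wrapper is total over complete records", {
  tr <- synthetic_truth(13)
  dat <- generate_participants(tr, 120)
  staged <- stage_participants(dat)
  expect_equal(nrow(staged), 120L)
  expect_true(all(staged$stage %in% 0:4))
  # clinical-history rows are always stage 4
  clin <- staged$heart_failure == 1 | staged$coronary_artery_disease == 1 |
    staged$heart_attack == 1 | staged$stroke == 1
  expect_true(all(staged$stage[clin] == 4L))
})
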