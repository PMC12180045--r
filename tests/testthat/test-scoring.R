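test_that("energy standardization rescales grams and fixes percent energy", {
  p <- intake_profile(c(eggs = 9.04, added_sugars = 14.64),
                      energy_basis = 1000,
                      units = c(eggs = "grams_per_day",
                                added_sugars = "percent_energy"))
  s <- standardize_energy(p, 2500)
  expect_equal(s$intakes[["eggs"]], 22.6)
  expect_equal(s$intakes[["added_sugars"]], 14.64)
  expect_equal(s$energy_basis, 2500)
  # identity basis leaves the profile unchanged
  expect_equal(standardize_energy(p, 1000), p)
  expect_error(standardize_energy(p, -5), "> 0")

  # symbolic consistency on random profiles: scale by target/basis
  set.seed(11)
  for (i in 1:20) {
    basis <- runif(1, 500, 3000); target <- runif(1, 500, 3000)
    v <- runif(5, 0, 400); names(v) <- letters[1:5]
    un <- setNames(sample(c("grams_per_day", "percent_energy"), 5, TRUE),
                   letters[1:5])
    v[un == "percent_energy"] <- pmin(v[un == "percent_energy"], 100)
    pr <- intake_profile(v, basis, units = un)
    sc <- standardize_energy(pr, target)
    g <- un == "grams_per_day"
    expect_equal(sc$intakes[g], v[g] * target / basis, tolerance = 1e-12)
    expect_equal(sc$intakes[!g], v[!g], tolerance = 1e-12)
  }
})

test_that("component scoring reproduces the stated curve anchors", {
  meat <- component_spec("red_processed_meat", "bidirectional",
                         optimal_low = 14, max_ref = 28)
  expect_equal(score_component(0, meat), 0)       # zero intake scores zero
  expect_equal(score_component(14, meat), 10)     # peak at the optimum
  expect_equal(score_component(21, meat), 5)      # midpoint of the fall
  expect_equal(score_component(28, meat), 0)
  expect_equal(score_component(100, meat), 0)

  sugars <- component_spec("added_sugars", "moderation",
                           unit = "percent_energy", max_ref = 5)
  expect_equal(score_component(0, sugars), 10)    # unidirectional floor
  expect_equal(score_component(5, sugars), 0)
  expect_equal(score_component(2.5, sugars), 5)

  grains <- component_spec("whole_grains", "adequacy", optimal_low = 232)
  expect_equal(score_component(232, grains), 10)
  expect_equal(score_component(116, grains), 5)
  expect_equal(score_component(500, grains), 10)  # no penalty above optimum
})

test_that("component scores match an independent dense-grid oracle and stay bounded", {
  set.seed(101)
  for (i in 1:400) {
    sp <- random_component_spec()
    x <- c(0, sp$optimal_low, sp$optimal_high,
           if (!is.na(sp$max_ref)) sp$max_ref, runif(25, 0, 400))
    expect_equal(score_component(x, sp), grid_score_oracle(sp, x),
                 tolerance = 1e-12)
  }
  # bulk boundedness
  sp <- random_component_spec()
  x <- runif(1e5, 0, 1000)
  s <- score_component(x, sp)
  expect_true(all(s >= 0 & s <= 10))
})

test_that("scoring curves are monotone in the documented directions", {
  set.seed(5)
  x <- sort(runif(500, 0, 300))
  for (i in 1:30) {
    sp <- random_component_spec()
    s <- score_component(x, sp)
    if (sp$kind == "adequacy") {
      expect_true(all(diff(s) >= -1e-12))
    } else if (sp$kind == "moderation") {
      expect_true(all(diff(s) <= 1e-12))
    } else {
      below <- x <= sp$optimal_low
      above <- x >= sp$optimal_high
      expect_true(all(diff(s[below]) >= -1e-12))
      expect_true(all(diff(s[above]) <= 1e-12))
    }
  }
})

test_that("profile scoring sums components across both index variants", {
  full <- phdi_config("full14")
  gdd <- phdi_config("gdd13")
  expect_equal(score_profile(optimal_profile(full), full)$total, 140)
  expect_equal(score_profile(optimal_profile(gdd), gdd)$total, 130)

  # all-zero intakes under the bidirectional modification: only the two
  # unidirectional moderation components retain their maximum
  zeros <- setNames(rep(0, 13), names(gdd$components))
  r0 <- score_profile(intake_profile(zeros, 2500, config = gdd), gdd)
  expect_equal(r0$total, 20)
  expect_equal(unname(r0$per_component[c("saturated_fats", "added_sugars")]),
               c(10, 10))
  expect_true(all(r0$per_component[setdiff(names(gdd$components),
    c("saturated_fats", "added_sugars"))] == 0))

  # total equals the sum of components; each component in [0, 10]
  set.seed(21)
  for (i in 1:25) {
    v <- runif(13, 0, 500); names(v) <- names(gdd$components)
    v[c("saturated_fats", "added_sugars")] <- runif(2, 0, 60)
    r <- score_profile(intake_profile(v, 2500, config = gdd), gdd)
    expect_equal(r$total, sum(r$per_component), tolerance = 1e-9)
    expect_true(all(r$per_component >= 0 & r$per_component <= 10))
  }

  expect_error(score_profile(intake_profile(c(eggs = 5), 2500,
                                            units = c(eggs = "grams_per_day")),
                             gdd), "missing intake")
})

test_that("scoring is invariant to the reporting basis of the same diet", {
  gdd <- phdi_config("gdd13")
  set.seed(31)
  units <- vapply(gdd$components, `[[`, "", "unit")
  for (i in 1:10) {
    v2500 <- runif(13, 0, 400); names(v2500) <- names(gdd$components)
    v2500[units == "percent_energy"] <- runif(sum(units == "percent_energy"), 0, 40)
    basis <- runif(1, 600, 2400)
    valt <- v2500
    valt[units == "grams_per_day"] <-
      valt[units == "grams_per_day"] * basis / 2500
    r1 <- score_profile(intake_profile(v2500, 2500, config = gdd), gdd)
    r2 <- score_profile(intake_profile(valt, basis, config = gdd), gdd)
    expect_equal(r1$total, r2$total, tolerance = 1e-9)
  }
})

test_that("stratum aggregation gives means and percentile intervals", {
  expect_equal(aggregate_stratum(c(40, 44))$mean, 42)
  a <- aggregate_stratum(rep(43, 5))
  expect_equal(c(a$ui_low, a$mean, a$ui_high), c(43, 43, 43))
  expect_error(aggregate_stratum(42), "at least 2 draws")
  expect_error(aggregate_stratum(c(1, 2), weights = c(0, 0)), "weights")
  # weighted mean
  expect_equal(aggregate_stratum(c(40, 50), weights = c(3, 1))$mean, 42.5)

  # Monte-Carlo percentiles against the closed-form Normal quantiles
  set.seed(77)
  draws <- rnorm(10000, 43, 1)
  ag <- aggregate_stratum(draws)
  expect_equal(ag$ui_low, qnorm(0.025, 43, 1), tolerance = 0.1)
  expect_equal(ag$ui_high, qnorm(0.975, 43, 1), tolerance = 0.1)
  expect_true(ag$ui_low <= median(draws) && median(draws) <= ag$ui_high)
})

test_that("difference decomposition is additive and localizes contrasts", {
  comps <- names(phdi_config("gdd13")$components)
  base <- setNames(runif(13, 0, 10), comps)
  expect_equal(decompose_difference(base, base)$total_difference, 0)

  shifted <- base; shifted[["whole_fruits"]] <- base[["whole_fruits"]] + 0.96
  d <- decompose_difference(shifted, base)
  expect_equal(d$contributions[["whole_fruits"]], 0.96)
  expect_equal(sum(abs(d$contributions[setdiff(comps, "whole_fruits")])), 0)
  expect_equal(d$total_difference, 0.96)

  set.seed(55)
  for (i in 1:20) {
    a <- setNames(runif(13, 0, 10), comps)
    b <- setNames(runif(13, 0, 10), sample(comps))  # permuted names
    d <- decompose_difference(a, b)
    expect_equal(d$total_difference, sum(d$contributions), tolerance = 1e-9)
    expect_equal(d$total_difference, sum(a) - sum(b), tolerance = 1e-9)
  }
  expect_error(decompose_difference(base, base[-1]), "differ")
})
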