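test_that("reference doses derive from NOAEL over safety factor", {
  rd <- reference_dose_from_noael(10, 500)
  expect_equal(rd$adi, 0.02)
  expect_equal(rd$arfd, 0.02)
  expect_equal(reference_dose_from_noael(3.7, 1)$adi, 3.7)
  expect_equal(reference_dose_from_noael(0.1, 100)$adi, 0.001)
  expect_error(reference_dose_from_noael(-1, 10), "positive")
  expect_error(reference_dose_from_noael(10, 0), "positive")
})

test_that("positive-normal sampling preserves the mean and degenerates at cv 0", {
  expect_equal(sample_positive_normal(0.22, 0, 7), rep(0.22, 7))
  x <- sample_positive_normal(1, 0.1, 1e5, seed = 42)
  expect_lt(abs(mean(x) - 1), 3 * 0.1 / sqrt(1e5))
  expect_true(all(x > 0))
  # heavy truncation still yields positive draws only
  y <- sample_positive_normal(0.5, 0.9, 5000, seed = 7)
  expect_true(all(y > 0))
  expect_error(sample_positive_normal(-1, 0.1, 10), "positive")
  # determinism
  expect_identical(sample_positive_normal(2, 0.1, 50, seed = 3),
                   sample_positive_normal(2, 0.1, 50, seed = 3))
})

test_that("truncated-normal quantiles match their Monte Carlo counterparts", {
  q <- truncated_normal_quantile(c(0.025, 0.5, 0.975), 0.22, 0.1)
  expect_true(all(diff(q) > 0))
  x <- sample_positive_normal(0.22, 0.1, 1e5, seed = 12)
  mc <- quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
  expect_equal(mc, q, tolerance = 0.005)
  expect_equal(truncated_normal_quantile(0.3, 5, 0), 5)
})

test_that("concentration sampling reproduces the substituted empirical distribution", {
  all_nd <- make_records(rep(NA_real_, 6), lod = 0.01)
  expect_equal(sample_concentration(all_nd, 20, seed = 1), rep(0.005, 20))

  single <- make_records(5.2, category = "cereal")
  expect_equal(sample_concentration(single, 10, seed = 1), rep(5.2, 10))

  two <- make_records(c(NA, 0.1), lod = 0.01)
  draws <- sample_concentration(two, 1e4, seed = 5)
  frac <- mean(draws == 0.1)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1e4))
  expect_true(all(draws %in% c(0.005, 0.1)))

  expect_error(sample_concentration(make_records(numeric(0)), 5), "non-empty")
})

test_that("fitted concentration model mixes a censored mass with a lognormal tail", {
  specs <- default_specs()[6, ] # summer squash: moderate DF, feasible tail
  s <- generate_survey(specs, seed = 44)
  draws <- sample_concentration(s, 5000, seed = 2, model = "lognormal_fitted")
  half_lod <- s$lod[1] / 2
  expect_true(all(draws >= half_lod))
  expect_true(all(draws[draws > half_lod] >= s$loq[1]))
  df_emp <- mean(!s$censored)
  expect_lt(abs(mean(draws > half_lod) - df_emp), 3 * sqrt(df_emp * (1 - df_emp) / 5000))
})

test_that("chronic risk reduces to the closed form in the degenerate limit", {
  # one concentration value per category, cv = 0: CR = sum(c_f q_f) / (w ADI)
  profile <- flat_profile(intake = 0.45, bw = 60, cv = 0)
  recs <- list(
    vegetables = make_records(0.02),
    fruits = make_records(0.02, category = "fruit"),
    cereals = make_records(0.02, category = "cereal"),
    potatoes = make_records(0.02, category = "potato")
  )
  cfg <- simulation_config(n_iter = 500, seed = 2, cv = 0)
  cr <- chronic_risk(profile, recs, cfg)
  # per category: 0.45 * 0.02 / (60 * 0.02) = 0.0075
  expect_equal(unname(cr$percentiles), rep(4 * 0.0075, 4))
  expect_equal(unique(cr$samples), 4 * 0.0075)
  expect_equal(sum(cr$contributions), 1)
  expect_equal(unname(cr$contributions), rep(0.25, 4))

  expect_error(chronic_risk(profile, recs[1:3], cfg), "potatoes")
})

test_that("chronic risk scales linearly with concentration under a fixed seed", {
  s <- generate_survey(default_specs()[c(1, 38, 29, 64), ], seed = 19)
  profile <- default_consumption()$adult_female
  cfg <- simulation_config(n_iter = 400, seed = 77)
  base <- chronic_risk(profile, s, cfg)
  doubled <- s
  doubled$concentration <- doubled$concentration * 2
  doubled$lod <- doubled$lod * 2 # halves substitute at lod/2 too
  doubled$loq <- doubled$loq * 2
  twice <- chronic_risk(profile, doubled, cfg)
  expect_equal(twice$samples, 2 * base$samples)
})

test_that("contributions equal intake shares when concentrations are equal", {
  profile <- consumption_profile(
    "adult_male",
    intake_mean = c(vegetables = 0.4, fruits = 0.2, cereals = 0.3, potatoes = 0.1),
    body_weight_mean = 63, cv = 0
  )
  recs <- lapply(c(vegetables = "vegetable", fruits = "fruit",
                   cereals = "cereal", potatoes = "potato"),
                 function(cat) make_records(0.05, category = cat))
  cr <- chronic_risk(profile, recs, simulation_config(n_iter = 50, seed = 1, cv = 0))
  expect_equal(unname(cr$contributions), c(0.4, 0.2, 0.3, 0.1))
})

test_that("acute risk matches hand arithmetic and is linear in concentration", {
  profile <- flat_profile(intake = 0.2, bw = 20, cv = 0)
  cfg <- simulation_config(n_iter = 300, seed = 4, cv = 0)
  ar <- acute_risk(profile, make_records(2, category = "cereal"), "cereals", cfg)
  expect_equal(unique(ar$samples), 1.0) # 2 * 0.2 / (20 * 0.02)
  expect_equal(unname(ar$percentiles), rep(1.0, 4))

  ar52 <- acute_risk(profile, make_records(5.2, category = "cereal"), "cereals", cfg)
  ar20 <- acute_risk(profile, make_records(2.0, category = "cereal"), "cereals", cfg)
  expect_equal(ar20$samples / ar52$samples, rep(2.0 / 5.2, cfg$n_iter))
})

test_that("the Monte Carlo acute distribution converges to the analytic upper-bound inputs", {
  profile <- default_consumption()$children_2_7
  recs <- make_records(c(NA, NA, 0.02, 0.5, 5.2, 1.1, NA, 0.08), category = "cereal")
  cfg <- simulation_config(n_iter = 1e5, seed = 9)
  ar <- acute_risk(profile, recs, "cereals", cfg)

  # the empirical concentration quantile used by both routes is identical
  q_conc <- quantile(substitute_censored(recs), 0.975, type = 7, names = FALSE)
  expect_equal(
    ar$ar_upper,
    q_conc * truncated_normal_quantile(0.975, 0.22, 0.1) /
      (truncated_normal_quantile(0.025, 18.5, 0.1) * 0.02)
  )

  # MC intake and body-weight quantiles converge on the analytic ones
  intake <- sample_positive_normal(0.22, 0.1, 1e5,
                                   seed = child_seed(9, "children_2_7/cereals/intake"))
  expect_equal(quantile(intake, 0.975, names = FALSE),
               truncated_normal_quantile(0.975, 0.22, 0.1),
               tolerance = 0.01)
})

test_that("percentile algebra for the joint extreme combination is exact at the corners", {
  expect_equal(combined_exceedance_percentile(0.975, 0.975, 0.025),
               1 - 0.025 * 0.025 * 0.025)
  expect_equal(combined_exceedance_percentile(0, 0, 1), 0)
  expect_equal(combined_exceedance_percentile(1, 1, 0.7), 1)
})

test_that("exceedance fractions count strict exceedances", {
  d <- c(0.05, 0.15, 1.5, 0.2)
  expect_equal(unname(exceedance_fractions(d, c(0.1, 1))), c(0.75, 0.25))
  expect_equal(unname(exceedance_fractions(rep(0, 5), c(0.1, 1))), c(0, 0))
  expect_equal(unname(exceedance_fractions(d, 0.01)), 1.0)
  expect_error(exceedance_fractions(numeric(0)), "non-empty")
})

test_that("default consumption profiles decline in intake per body weight with age", {
  profs <- default_consumption()
  expect_named(profs, c("children_2_7", "adolescent_male", "adolescent_female",
                        "adult_male", "adult_female"))
  for (cc in c("vegetables", "fruits", "cereals", "potatoes")) {
    ratio <- vapply(profs, function(p) p$intake_mean[[cc]] / p$body_weight_mean, 1.0)
    child <- ratio[["children_2_7"]]
    adol <- ratio[c("adolescent_male", "adolescent_female")]
    adult <- ratio[c("adult_male", "adult_female")]
    expect_gt(child, max(adol))
    expect_gt(min(adol), max(adult))
  }
  # the two intakes national diet studies most often quote
  expect_equal(profs$children_2_7$intake_mean[["vegetables"]], 0.19)
  expect_equal(profs$adult_male$intake_mean[["cereals"]], 0.45)
})
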