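test_that("cohort specs validate rates and prevalence", {
  expect_error(cohort_spec(target_prevalence = 0), "prevalence")
  expect_error(cohort_spec(missingness_rates = list(bmi = 1.2)), "rates")
  expect_error(cohort_spec(effect_coefficients = c(nope = 1)),
               "unknown effect")
})

test_that("a cohort has two knees per participant at every visit", {
  ct <- simulate_cohort(cohort_spec(n_participants = 5, seed = 3))
  expect_equal(nrow(ct), 5 * 2 * 3)
  for (v in c("V0", "V3", "V6"))
    expect_equal(sum(ct$visit == v), 10)
  expect_true(all(table(ct$participant_id, ct$side) == 3))
  expect_true(all(descriptor_names() %in% colnames(ct)))
})

test_that("JSN grades are monotone non-decreasing across visits", {
  ct <- simulate_cohort(cohort_spec(n_participants = 200, seed = 8,
                                    missingness_rates = list()))
  wide <- reshape(ct[, c("participant_id", "side", "visit", "jsnm", "jsnl")],
                  idvar = c("participant_id", "side"), timevar = "visit",
                  direction = "wide")
  expect_true(all(wide$jsnm.V0 <= wide$jsnm.V3 &
                    wide$jsnm.V3 <= wide$jsnm.V6))
  expect_true(all(wide$jsnl.V0 <= wide$jsnl.V3 &
                    wide$jsnl.V3 <= wide$jsnl.V6))
  # at most +1 per interval
  expect_lte(max(wide$jsnm.V6 - wide$jsnm.V3), 1)
  expect_true(all(wide$jsnm.V6 <= 3 & wide$jsnl.V6 <= 3))
})

test_that("cohort simulation is seeded-deterministic", {
  sp <- cohort_spec(n_participants = 50, seed = 21)
  expect_identical(as.data.frame(simulate_cohort(sp)),
                   as.data.frame(simulate_cohort(sp)))
})

test_that("intercept calibration matches closed forms at zero slopes", {
  sp05 <- cohort_spec(n_participants = 4000, seed = 5,
                      effect_coefficients = c(KL = 0),
                      target_prevalence = 0.5)
  expect_lt(abs(calibrate_intercept(sp05)), 0.15)
  sp12 <- cohort_spec(n_participants = 4000, seed = 5,
                      effect_coefficients = c(KL = 0),
                      target_prevalence = 0.12)
  expect_lt(abs(calibrate_intercept(sp12) - log(0.12 / 0.88)), 0.1)
})

test_that("calibration holds empirically with nonzero slopes", {
  sp <- cohort_spec(n_participants = 3000, seed = 31,
                    target_prevalence = 0.12)
  ct <- simulate_cohort(sp)
  latent <- attr(ct, "latent")
  emp <- mean(latent$jsnm_v6 > latent$jsnm_v3)
  expect_lt(abs(emp - 0.12), 0.02)
})

test_that("scenario-1 prevalence matches the calibration target", {
  sp <- cohort_spec(n_participants = 2000, seed = 17,
                    effect_coefficients = c(delta_tbt_composite = 0),
                    target_prevalence = 0.10)
  latent <- attr(simulate_cohort(sp), "latent")
  s1 <- (latent$jsnm_v6 > latent$jsnm_v3) | (latent$jsnl_v6 > latent$jsnl_v3)
  expect_lt(abs(mean(s1) - 0.10), 0.02)
})

test_that("unattainable prevalence targets fail after calibration", {
  sp <- cohort_spec(n_participants = 500, seed = 2,
                    effect_coefficients = c(KL = 0),
                    target_prevalence = 0.999)
  expect_error(calibrate_intercept(sp), "unattainable|tolerance")
})

test_that("missingness injection respects the configured rates", {
  sp <- cohort_spec(n_participants = 2000, seed = 9,
                    missingness_rates = list(bmi = 0.1, jsnl = 0.05))
  ct <- simulate_cohort(sp)
  expect_equal(mean(is.na(ct$bmi[ct$visit != "V6"])), 0.1,
               tolerance = 0.25)
  expect_equal(mean(is.na(ct$jsnl)), 0.05, tolerance = 0.25)
  expect_false(anyNA(ct$age))
})

test_that("signal descriptors carry the delta composite, others do not", {
  sp <- cohort_spec(n_participants = 1500, seed = 13)
  ct <- simulate_cohort(sp)
  latent <- attr(ct, "latent")
  latent <- latent[order(latent$participant_id, latent$side), ]
  v0 <- ct[ct$visit == "V0", ]
  v3 <- ct[ct$visit == "V3", ]
  sig <- sp$signal_descriptors[1]
  noise <- setdiff(descriptor_names(), sp$signal_descriptors)[1]
  d_sig <- v3[[sig]] - v0[[sig]]
  d_noise <- v3[[noise]] - v0[[noise]]
  expect_gt(cor(d_sig, latent$delta_tbt_composite), 0.5)
  expect_lt(abs(cor(d_noise, latent$delta_tbt_composite)), 0.1)
})

test_that("cohort CSV round trip preserves values and missing fields", {
  sp <- cohort_spec(n_participants = 20, seed = 4,
                    missingness_rates = list(bmi = 0.2))
  ct <- simulate_cohort(sp)
  path <- file.path(tempdir(), "cohort.csv")
  write_cohort(ct, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), nrow(ct))
  expect_equal(back$jsnm, ct$jsnm)
  expect_equal(sum(is.na(back$bmi)), sum(is.na(ct$bmi)))
  expect_equal(back[[descriptor_names()[10]]], ct[[descriptor_names()[10]]])
  unlink(path)
})
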