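test_that("the model grid enumerates the 18 printed block combinations", {
  models <- enumerate_models()
  expect_length(models, 18)
  expect_equal(vapply(models, `[[`, integer(1), "id"), 1:18)
  blocks <- lapply(models, `[[`, "blocks")
  expect_identical(blocks[[1]], "CLIN")
  expect_identical(blocks[[2]], "CLINW")
  expect_identical(blocks[[5]], c("CLIN", "KL", "JSNM"))
  expect_identical(blocks[[6]], "TBT")
  expect_identical(sort(blocks[[11]]), sort(c("dTBT", "CLIN", "KL", "JSNM")))
  expect_identical(sort(blocks[[15]]),
                   sort(c("TBT", "dTBT", "CLIN", "KL", "JSNM")))
  expect_identical(sort(blocks[[18]]),
                   sort(c("TBT", "dTBT", "dCLIN", "dKL", "JSNM")))
  # delta JSNM is never a predictor block
  expect_false(any(vapply(blocks, function(b) "dJSNM" %in% b, logical(1))))
  # texture blocks and only texture blocks are selectable
  for (m in models) {
    expect_identical(m$selectable_blocks, intersect(m$blocks,
                                                    c("TBT", "dTBT")))
    expect_identical(sort(c(m$selectable_blocks, m$forced_blocks)),
                     sort(m$blocks))
  }
  expect_error(model_spec(19), "1..18")
})

test_that("design matrices encode blocks as specified", {
  ct <- simulate_cohort(cohort_spec(n_participants = 60, seed = 41,
                                    missingness_rates = list()))
  ds <- build_analysis_dataset(ct, 1)
  d5 <- model_design(model_spec(5), ds)
  expect_identical(colnames(d5$x),
                   c("(Intercept)", "age", "gender_f", "bmi", "kl", "jsnm"))
  expect_length(d5$selectable, 0)
  expect_true(all(d5$x[, "gender_f"] %in% c(0, 1)))
  d15 <- model_design(model_spec(15), ds)
  expect_length(d15$selectable, 128)
  expect_identical(d15$forced,
                   c("(Intercept)", "age", "gender_f", "bmi", "kl", "jsnm"))
  dm <- model_design(model_spec(6), ds, compartments = "medial")
  expect_length(dm$selectable, 24)
  expect_identical(dm$forced, "(Intercept)")
})

test_that("unpenalised fits match stats::glm to numerical precision", {
  td <- toy_logistic(n = 400, seed = 2)
  ref <- glm(td$y ~ td$x - 1, family = binomial)
  fit <- tbtprog:::cpp_logistic_fit(td$x, td$y)
  expect_equal(as.numeric(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-7)
  expect_equal(fit$aic, AIC(ref), tolerance = 1e-8)
})

test_that("stepwise AIC lowers AIC monotonically to a local minimum", {
  td <- toy_logistic(n = 500, seed = 3)
  st <- stepwise_aic(td$x, td$y, forced = c("(Intercept)", "z1"),
                     selectable = c("z2", "signal", "noise"))
  expect_true(all(diff(st$aic_trace) < 0))
  expect_true(all(c("(Intercept)", "z1") %in% st$selected))
  # brute-force local-minimum certificate: no single add/drop improves
  sel <- st$selected
  aic_of <- function(cols) {
    f <- glm.fit(td$x[, cols, drop = FALSE], td$y,
                 family = binomial())
    f$aic
  }
  expect_equal(st$aic, aic_of(sel), tolerance = 1e-6)
  for (drop in setdiff(sel, c("(Intercept)", "z1")))
    expect_gte(aic_of(setdiff(sel, drop)), st$aic - 1e-6)
  for (add in setdiff(c("z2", "signal", "noise"), sel))
    expect_gte(aic_of(c(sel, add)), st$aic - 1e-6)
})

test_that("stepwise AIC keeps signal and sheds noise at the known rates", {
  keep_signal <- logical(50); keep_noise <- logical(50)
  for (i in 1:50) {
    td <- toy_logistic(n = 500, beta_signal = 1.0, seed = 100 + i)
    st <- stepwise_aic(td$x, td$y, forced = c("(Intercept)", "z1"),
                       selectable = c("signal", "noise"))
    keep_signal[i] <- "signal" %in% st$selected
    keep_noise[i] <- "noise" %in% st$selected
  }
  expect_gt(mean(keep_signal), 0.9)
  expect_lt(mean(keep_noise), 0.2)
})

test_that("stepwise with no selectable columns returns the forced model", {
  td <- toy_logistic(n = 300, seed = 5)
  st <- stepwise_aic(td$x, td$y, forced = colnames(td$x),
                     selectable = character())
  expect_identical(st$selected, colnames(td$x))
  ref <- glm(td$y ~ td$x - 1, family = binomial)
  expect_equal(unname(st$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
})

test_that("separated data falls back to a flagged stabilised fit", {
  x <- cbind("(Intercept)" = 1, sep = c(rep(-1, 20), rep(1, 20)))
  y <- c(rep(0, 20), rep(1, 20))
  fit <- tbtprog:::cpp_logistic_fit(x, y)
  expect_true(fit$ridged)
  expect_true(all(is.finite(fit$coefficients)))
})

test_that("koa_fit objects fit, predict and print coherently", {
  ct <- simulate_cohort(cohort_spec(n_participants = 400, seed = 43,
                                    missingness_rates = list()))
  ds <- build_analysis_dataset(ct, 2)
  fit <- fit_progression_model(5, ds)
  expect_s3_class(fit, "koa_fit")
  expect_named(coef(fit)[1], "(Intercept)")
  p <- predict(fit, ds)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(predict(fit, ds, type = "link"), qlogis(p),
               tolerance = 1e-10)
  # against glm on the same design
  ref <- glm(outcome ~ age + I(gender == "F") + bmi + kl + jsnm,
             family = binomial, data = ds)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  expect_output(print(fit), "Model 5")
  fit15 <- fit_progression_model(15, ds)
  expect_true(all(fit15$forced %in% fit15$selected))
  expect_output(print(summary(fit15)), "Coefficients")
})

test_that("flagged descriptors are mean-imputed from training data only", {
  x <- cbind("(Intercept)" = 1, a = c(1, 2, NA, 4), b = c(NA, 1, 1, 1))
  imp <- tbtprog:::impute_columns(x)
  expect_equal(unname(imp$x[3, "a"]), mean(c(1, 2, 4)))
  expect_equal(unname(imp$x[1, "b"]), 1)
  new <- cbind("(Intercept)" = 1, a = NA_real_, b = 5)
  expect_equal(unname(tbtprog:::impute_columns(new, imp$means)$x[1, "a"]),
               mean(c(1, 2, 4)))
})
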