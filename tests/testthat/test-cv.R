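# brute-force AUC oracle: pairwise comparisons with ties counted 1/2
auc_bruteforce <- function(p, y) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

test_that("rank AUC equals the brute-force pairwise oracle", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))  # both classes guaranteed
    p <- round(runif(n), sample(c(1, 2, 8), 1))  # ties at low precision
    expect_equal(auc_mann_whitney(p, y), auc_bruteforce(p, y))
  }
  expect_equal(auc_mann_whitney(c(0.1, 0.9), c(0, 1)), 1)
  expect_error(auc_mann_whitney(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("classification metrics follow their definitions", {
  y <- c(1, 1, 0, 0)
  m <- classification_metrics(c(0.9, 0.8, 0.1, 0.2), y)
  expect_equal(m$bacc, 1)       # sens = spec = 1
  expect_equal(m$auc, 1)
  m2 <- classification_metrics(c(0.1, 0.2, 0.05, 0.15), y)
  expect_equal(m2$bacc, 0.5)    # sens = 0, spec = 1
  expect_true(is.na(m2$ppv))    # no positive predictions -> NaN convention
  expect_equal(m2$npv, 0.5)
  expect_identical(m2$precision, m2$ppv)
  m3 <- classification_metrics(c(0.9, 0.8, 0.7, 0.6), y)
  expect_equal(m3$bacc, 0.5)    # sens = 1, spec = 0
  expect_true(is.na(m3$npv))
})

test_that("stratified folds partition each class evenly", {
  set.seed(3)
  y <- rbinom(200, 1, 0.15)
  f <- tbtprog:::stratified_folds(y, 10)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(table(f) %in% c(19, 20, 21)))
  pos_per_fold <- table(f[y == 1])
  expect_lte(max(pos_per_fold) - min(pos_per_fold), 1)
})

test_that("repeated CV tests every sample exactly once per repeat", {
  ct <- simulate_cohort(cohort_spec(n_participants = 300, seed = 47))
  ds <- build_analysis_dataset(ct, 1)
  cv <- repeated_cv(5, ds, folds = 5, repeats = 3, seed = 2)
  expect_equal(length(cv$oof), nrow(ds))
  expect_true(all(cv$oof > 0 & cv$oof < 1))
  expect_equal(length(cv$per_repeat_auc), 3)
  expect_true(cv$auc_ci[1] <= cv$auc && cv$auc <= cv$auc_ci[2])
  # determinism under the same master seed
  cv2 <- repeated_cv(5, ds, folds = 5, repeats = 3, seed = 2)
  expect_identical(cv$oof, cv2$oof)
  expect_error(repeated_cv(5, ds[ds$outcome == 0, ][1:40, ], folds = 10,
                           repeats = 1),
               "each class")
})

test_that("perfectly separable data drives AUC and BACC to 1", {
  n <- 200
  ds <- data.frame(
    participant_id = sprintf("P%03d", 1:n), side = "R",
    age = 60, gender = rep(c("F", "M"), n / 2), bmi = 28, womac_pain = 3,
    kl = 2, jsnm = 1, jsnl = 0, delta_bmi = 0, delta_womac = 0,
    delta_kl = 0, outcome = rep(0:1, each = n / 2))
  set.seed(10)
  ds$bmi <- round(rnorm(n, 28, 3), 1)
  ds$age <- 55 + 10 * ds$outcome  # age separates the classes exactly
  cv <- repeated_cv(1, ds, folds = 5, repeats = 2, seed = 4)
  expect_gt(cv$auc, 0.999)
  expect_gt(cv$bacc, 0.999)
})

test_that("ROC comparison is antisymmetric with symmetric p-values", {
  set.seed(6)
  y <- rbinom(120, 1, 0.4)
  pa <- plogis(rnorm(120) + 0.8 * y)
  pb <- plogis(rnorm(120) + 0.3 * y)
  ab <- compare_roc(pa, pb, labels = y)
  ba <- compare_roc(pb, pa, labels = y)
  expect_equal(ab$delta_auc, -ba$delta_auc)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  expect_true(ab$p_value > 0 && ab$p_value <= 1)
  same <- compare_roc(pa, pa, labels = y)
  expect_equal(same$delta_auc, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_roc(pa, pb, labels = rep(1, 120)), "both classes")
})

test_that("selection frequencies mark signal ROIs above noise ROIs", {
  sp <- cohort_spec(n_participants = 1500, seed = 53,
                    effect_coefficients = c(delta_tbt_composite = 2.0))
  ds <- build_analysis_dataset(simulate_cohort(sp), 2)
  cv <- repeated_cv(11, ds, folds = 5, repeats = 4, seed = 9)
  m <- selection_frequency_map(cv)
  expect_equal(nrow(m), 64)            # the 64 delta descriptors
  expect_true(all(m$frequency >= 0 & m$frequency <= 1))
  is_sig <- sub("^d", "", m$feature) %in% sp$signal_descriptors
  expect_lt(wilcox.test(m$frequency[is_sig], m$frequency[!is_sig],
                        alternative = "greater",
                        exact = FALSE)$p.value, 0.05)
  # a model without selectable blocks has an empty map
  cv5 <- repeated_cv(5, ds, folds = 5, repeats = 1, seed = 9)
  expect_equal(nrow(selection_frequency_map(cv5)), 0)
})

test_that("pre-CV selection mode reuses one feature subset across folds", {
  sp <- cohort_spec(n_participants = 500, seed = 59)
  ds <- build_analysis_dataset(simulate_cohort(sp), 1)
  cv <- repeated_cv(6, ds, folds = 5, repeats = 2, seed = 3,
                    selection = "pre")
  expect_s3_class(cv, "koa_cv")
  # frequencies are 0/1 because the subset is fixed before CV
  expect_true(all(cv$selection_frequency %in% c(0, 1)))
})
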