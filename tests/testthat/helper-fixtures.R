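# Programmatic micro-fixtures used across test files.

# Three visit rows (V0/V3/V6) for one knee, with the columns the selection
# pipeline needs. Grade arguments are length-3 vectors (V0, V3, V6).
knee_rows <- function(pid, side, kl = 2, womac = 3,
                      jsnm = c(0, 0, 0), jsnl = c(0, 0, 0),
                      age = 60, gender = "F", bmi = 28, qc = TRUE,
                      womac_v3 = womac) {
  data.frame(participant_id = pid, side = side, visit = c("V0", "V3", "V6"),
             age = age, gender = gender, bmi = bmi,
             womac_pain = c(womac, womac_v3, NA),
             kl = c(kl, kl, NA), jsnm = jsnm, jsnl = jsnl,
             qc_pass = qc, stringsAsFactors = FALSE)
}

# A two-knee participant; per-knee overrides via lists.
participant_rows <- function(pid, right = list(), left = list()) {
  rbind(do.call(knee_rows, c(list(pid = pid, side = "R"), right)),
        do.call(knee_rows, c(list(pid = pid, side = "L"), left)))
}

# Small synthetic logistic dataset with named signal/noise columns, for
# stepwise-selection behaviour tests.
toy_logistic <- function(n = 500, beta_signal = 1.0, seed = 1) {
  set.seed(seed)
  x <- cbind("(Intercept)" = 1, z1 = rnorm(n), z2 = rnorm(n),
             signal = rnorm(n), noise = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.5 + 0.5 * x[, "z1"] +
                             beta_signal * x[, "signal"]))
  list(x = x, y = y)
}

# Deterministic ROI-ready image: landmarks horizontal, given texture.
flat_knee_image <- function(width = 820, height = 400, value = 0.5,
                            laterality = "R") {
  knee_image(matrix(value, height, width),
             landmark_medial = c(810, 100), landmark_lateral = c(10, 100),
             spacing_mm = 0.2, laterality = laterality)
}
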