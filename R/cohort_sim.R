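#' Specification of a synthetic longitudinal knee-OA cohort
#'
#' Defines the statistical structure of a simulated Osteoarthritis-
#' Initiative-like cohort: two knees per participant, clinical covariates
#' and WOMAC pain at V0/V3, KL grade at baseline, JSN grades (medial and
#' lateral, 0--3) at V0/V3/V6 evolving by upward-only +1 transitions, and 64
#' trabecular-texture descriptors per knee at V0 and V3. A latent
#' progression propensity, logit-linear in `effect_coefficients`, drives the
#' medial V3 to V6 transition; the intercept is calibrated by bisection so
#' the propensity-driven event matches `target_prevalence`.
#'
#' Recognised effect names: `delta_tbt_composite`, `tbt_v0_composite`
#' (latent composites loading on the designated signal descriptors), `KL`,
#' `JSNM_V0`, `BMI`, `age`, `gender`, `womac`, `delta_bmi` (all entered on
#' standardised scales, see [progression_features()]).
#'
#' @param n_participants Number of participants (2 knees each).
#' @param effect_coefficients Named numeric vector of log-odds coefficients.
#' @param target_prevalence Target propensity-driven progressor fraction,
#'   in (0, 1). Default 0.12 (radiographic JSN progression studies with
#'   comparable selection typically observe roughly 9--12% progressors).
#' @param missingness_rates Named list of completely-at-random missingness
#'   fractions per field (fields among `womac_pain`, `bmi`, `kl`, `jsnm`,
#'   `jsnl`).
#' @param grade_transition_rates Named list: `jsnm_v0v3`, `jsnl_v0v3`
#'   (background +1 probabilities from baseline to 24 months) and
#'   `jsnl_v3v6` (lateral background rate from 24 to 48 months).
#' @param kl_probs Baseline KL-grade distribution over grades 0--4.
#' @param signal_descriptors Character vector of descriptor column names
#'   that load on the latent composites (default: vertical-direction
#'   descriptors of the medial and lateral compartments).
#' @param seed Integer RNG seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 1000L,
                        effect_coefficients = c(delta_tbt_composite = 1.0,
                                                tbt_v0_composite = 0.4,
                                                KL = 0.35, JSNM_V0 = 0.35,
                                                BMI = 0.15, age = 0.1),
                        target_prevalence = 0.12,
                        missingness_rates = list(womac_pain = 0.02,
                                                 bmi = 0.02, jsnm = 0.01,
                                                 jsnl = 0.01),
                        grade_transition_rates = list(jsnm_v0v3 = 0.04,
                                                      jsnl_v0v3 = 0.03,
                                                      jsnl_v3v6 = 0.01),
                        kl_probs = c(0.15, 0.15, 0.35, 0.25, 0.10),
                        signal_descriptors = NULL,
                        seed = 1L) {
  if (!is.finite(target_prevalence) || target_prevalence <= 0 ||
      target_prevalence >= 1)
    stop("target_prevalence must lie in (0, 1)")
  rates <- c(unlist(missingness_rates), unlist(grade_transition_rates))
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  stopifnot(n_participants >= 1, length(kl_probs) == 5,
            abs(sum(kl_probs) - 1) < 1e-6)
  if (is.null(signal_descriptors))
    signal_descriptors <- grep("_v_", descriptor_names(c("medial",
                                                         "lateral")),
                               value = TRUE)
  known <- c("delta_tbt_composite", "tbt_v0_composite", "KL", "JSNM_V0",
             "JSNL_V0", "BMI", "age", "gender", "womac", "delta_bmi")
  bad <- setdiff(names(effect_coefficients), known)
  if (length(bad)) stop("unknown effect names: ", paste(bad, collapse = ", "))
  structure(list(n_participants = as.integer(n_participants),
                 knees_per_participant = 2L,
                 effect_coefficients = effect_coefficients,
                 target_prevalence = target_prevalence,
                 missingness_rates = missingness_rates,
                 grade_transition_rates = grade_transition_rates,
                 kl_probs = kl_probs,
                 signal_descriptors = signal_descriptors,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Standardising constants: fixed (not estimated from the sample) so that
# effect coefficients keep the same meaning at any cohort size.
.feat_center <- c(age = 61, BMI = 28.5, womac = 3, KL = 2.5, JSNM_V0 = 1,
                  JSNL_V0 = 0.5, gender = 0.58)
.feat_scale <- c(age = 9, BMI = 4.8, womac = 3)

#' Standardised progression features of knee-level records
#'
#' Maps knee-level baseline records to the standardised feature scales on
#' which the simulator's `effect_coefficients` are defined (age and BMI
#' z-scored against fixed population constants, grades centred, gender as a
#' centred female indicator, latent composites raw).
#'
#' @param knees Data frame with (a subset of) columns `age`, `gender`,
#'   `bmi`, `womac_v0`, `kl_v0`, `jsnm_v0`, `jsnl_v0`, `delta_bmi`,
#'   `tbt_v0_composite`, `delta_tbt_composite`.
#' @param names Which features to return (default: all available).
#' @return Numeric matrix, one row per knee.
#' @export
progression_features <- function(knees, names = NULL) {
  f <- list()
  if (!is.null(knees$age))
    f$age <- (knees$age - .feat_center["age"]) / .feat_scale["age"]
  if (!is.null(knees$gender))
    f$gender <- as.numeric(knees$gender == "F") - .feat_center["gender"]
  if (!is.null(knees$bmi))
    f$BMI <- (knees$bmi - .feat_center["BMI"]) / .feat_scale["BMI"]
  if (!is.null(knees$womac_v0))
    f$womac <- (knees$womac_v0 - .feat_center["womac"]) /
      .feat_scale["womac"]
  if (!is.null(knees$kl_v0)) f$KL <- knees$kl_v0 - .feat_center["KL"]
  if (!is.null(knees$jsnm_v0))
    f$JSNM_V0 <- knees$jsnm_v0 - .feat_center["JSNM_V0"]
  if (!is.null(knees$jsnl_v0))
    f$JSNL_V0 <- knees$jsnl_v0 - .feat_center["JSNL_V0"]
  if (!is.null(knees$delta_bmi)) f$delta_bmi <- knees$delta_bmi
  if (!is.null(knees$tbt_v0_composite))
    f$tbt_v0_composite <- knees$tbt_v0_composite
  if (!is.null(knees$delta_tbt_composite))
    f$delta_tbt_composite <- knees$delta_tbt_composite
  m <- do.call(cbind, f)
  if (!is.null(names)) {
    missing <- setdiff(names, colnames(m))
    if (length(missing))
      stop("features not derivable from `knees`: ",
           paste(missing, collapse = ", "))
    m <- m[, names, drop = FALSE]
  }
  m
}

# Knee-level pre-outcome state: covariates, baseline grades, V0->V3
# transitions, latent composites. Deterministic given spec (seeded).
simulate_cohort_state <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_participants
  nk <- 2L * n
  age <- round(pmin(pmax(stats::rnorm(n, 61, 9), 45), 79))
  gender <- ifelse(stats::runif(n) < 0.58, "F", "M")
  bmi <- round(pmin(pmax(stats::rnorm(n, 28.5, 4.8), 18), 45), 1)
  delta_bmi <- round(stats::rnorm(n, 0, 1.0), 1)

  pid <- rep(sprintf("P%05d", seq_len(n)), each = 2)
  side <- rep(c("R", "L"), n)
  kl_v0 <- sample(0:4, nk, replace = TRUE, prob = spec$kl_probs)
  # JSN grades at baseline depend on KL severity (upward shift with KL)
  jsn_probs <- rbind(c(0.85, 0.12, 0.03, 0.00),   # KL 0
                     c(0.75, 0.20, 0.05, 0.00),   # KL 1
                     c(0.45, 0.40, 0.14, 0.01),   # KL 2
                     c(0.15, 0.45, 0.35, 0.05),   # KL 3
                     c(0.05, 0.25, 0.45, 0.25))   # KL 4
  draw_grade <- function(kl) {
    vapply(kl, function(k) sample(0:3, 1, prob = jsn_probs[k + 1, ]),
           numeric(1))
  }
  jsnm_v0 <- draw_grade(kl_v0)
  jsnl_v0 <- draw_grade(kl_v0) * (stats::runif(nk) < 0.6)  # lateral rarer
  womac_v0 <- stats::rbinom(nk, 20, 0.15)
  womac_v3 <- pmin(pmax(womac_v0 + sample(-2:2, nk, replace = TRUE), 0), 20)

  r <- spec$grade_transition_rates
  jsnm_v3 <- jsnm_v0 + (jsnm_v0 < 3 & stats::runif(nk) < r$jsnm_v0v3)
  jsnl_v3 <- jsnl_v0 + (jsnl_v0 < 3 & stats::runif(nk) < r$jsnl_v0v3)

  tbt_v0_composite <- stats::rnorm(nk)
  delta_tbt_composite <- stats::rnorm(nk)

  knees <- data.frame(
    participant_id = pid, side = side,
    age = rep(age, each = 2), gender = rep(gender, each = 2),
    bmi = rep(bmi, each = 2), delta_bmi = rep(delta_bmi, each = 2),
    womac_v0 = womac_v0, womac_v3 = womac_v3,
    kl_v0 = kl_v0, jsnm_v0 = jsnm_v0, jsnl_v0 = jsnl_v0,
    jsnm_v3 = jsnm_v3, jsnl_v3 = jsnl_v3,
    tbt_v0_composite = tbt_v0_composite,
    delta_tbt_composite = delta_tbt_composite,
    stringsAsFactors = FALSE)
  beta <- spec$effect_coefficients
  eta0 <- if (length(beta))
    drop(progression_features(knees, names(beta)) %*% beta)
  else rep(0, nk)
  knees$eta0 <- eta0
  knees
}

#' Calibrate the progression-model intercept
#'
#' Finds, by bisection, the log-odds intercept at which the expected
#' propensity-driven medial V3 to V6 progression prevalence (knees already
#' at the JSNM ceiling cannot progress) equals `target_prevalence`. The
#' expectation is taken over the simulated knee-level covariates under the
#' spec's seed, so the result is deterministic.
#'
#' @param spec A `cohort_spec`.
#' @param tolerance Admissible |expected - target| (> 0), default 0.005.
#' @param max_iter Bisection iteration cap.
#' @return Scalar intercept (log-odds).
#' @export
calibrate_intercept <- function(spec, tolerance = 0.005, max_iter = 200L) {
  stopifnot(inherits(spec, "cohort_spec"), tolerance > 0)
  knees <- simulate_cohort_state(spec)
  can_progress <- knees$jsnm_v3 < 3
  f <- function(b0)
    mean(stats::plogis(b0 + knees$eta0) * can_progress) -
      spec$target_prevalence
  lo <- -20; hi <- 20
  if (f(hi) < 0 || f(lo) > 0) { lo <- -40; hi <- 40 }
  if (f(hi) < 0 || f(lo) > 0)
    stop("target prevalence ", spec$target_prevalence,
         " unattainable for these coefficients (calibration failure)")
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= tolerance && i > 1) return(mid)
    if (fm < 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  mid <- (lo + hi) / 2
  if (abs(f(mid)) > tolerance)
    stop("intercept calibration did not reach tolerance ", tolerance)
  mid
}

#' Simulate a longitudinal cohort table
#'
#' Generates the tidy cohort table: one row per (knee, visit) with visits
#' V0, V3, V6; columns `participant_id, side, visit, age, gender, bmi,
#' womac_pain, kl, jsnm, jsnl, qc_pass` and the 64 texture descriptor
#' columns `tbt_<roi>_<dir>_<scale>` (carried at V0 and V3; V6 rows hold
#' grades only). JSN grades move by at most +1 per interval and never
#' decrease. The baseline-to-V3 delta of the designated signal descriptors
#' loads on the latent `delta_tbt_composite`, which (with the other
#' configured effects) drives the medial V3 to V6 transition.
#'
#' @param spec A `cohort_spec`.
#' @return Data frame (class `cohort_table`) with
#'   `3 * 2 * n_participants` rows; attribute `intercept` records the
#'   calibrated intercept and `latent` the knee-level latent state.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  b0 <- calibrate_intercept(spec)
  knees <- simulate_cohort_state(spec)
  nk <- nrow(knees)
  set.seed(spec$seed + 1L)

  p_med <- stats::plogis(b0 + knees$eta0) * (knees$jsnm_v3 < 3)
  med_prog <- stats::runif(nk) < p_med
  lat_prog <- knees$jsnl_v3 < 3 &
    stats::runif(nk) < spec$grade_transition_rates$jsnl_v3v6
  knees$jsnm_v6 <- knees$jsnm_v3 + med_prog
  knees$jsnl_v6 <- knees$jsnl_v3 + lat_prog

  # descriptor panels at V0 and V3
  dn <- descriptor_names()
  sig <- dn %in% spec$signal_descriptors
  mu <- 0.45 + 0.15 * seq(0, 1, length.out = 64)  # per-descriptor level
  v0 <- matrix(stats::rnorm(nk * 64, sd = 0.04), nk, 64)
  v0 <- sweep(v0, 2, mu, "+") +
    0.04 * knees$tbt_v0_composite %o% as.numeric(sig)
  dlt <- matrix(stats::rnorm(nk * 64, sd = 0.03), nk, 64)
  dlt <- dlt + 0.03 * knees$delta_tbt_composite %o% as.numeric(sig)
  v3 <- v0 + dlt
  colnames(v0) <- colnames(v3) <- dn

  empty_tbt <- matrix(NA_real_, nk, 64, dimnames = list(NULL, dn))
  visit_row <- function(visit, womac, kl, jsnm, jsnl, tbt) {
    cbind(data.frame(participant_id = knees$participant_id,
                     side = knees$side, visit = visit,
                     age = knees$age, gender = knees$gender,
                     bmi = if (visit == "V3") knees$bmi + knees$delta_bmi
                           else knees$bmi,
                     womac_pain = womac, kl = kl, jsnm = jsnm, jsnl = jsnl,
                     qc_pass = TRUE, stringsAsFactors = FALSE),
          as.data.frame(tbt))
  }
  tab <- rbind(
    visit_row("V0", knees$womac_v0, knees$kl_v0, knees$jsnm_v0,
              knees$jsnl_v0, v0),
    visit_row("V3", knees$womac_v3, knees$kl_v0, knees$jsnm_v3,
              knees$jsnl_v3, v3),
    visit_row("V6", NA_integer_, NA_integer_, knees$jsnm_v6,
              knees$jsnl_v6, empty_tbt))
  tab <- tab[order(tab$participant_id, tab$side, tab$visit), ]
  rownames(tab) <- NULL

  # completely-at-random missingness per field (grades only at recorded
  # visits; V6 carries only jsnm/jsnl)
  mr <- spec$missingness_rates
  for (field in names(mr)) {
    if (!mr[[field]] > 0) next
    rows <- which(!is.na(tab[[field]]))
    drop <- rows[stats::runif(length(rows)) < mr[[field]]]
    tab[[field]][drop] <- NA
  }
  structure(tab, class = c("cohort_table", "data.frame"),
            intercept = b0, latent = knees)
}

#' Write / read a cohort table as tidy CSV
#'
#' Missing values are written as empty fields.
#'
#' @param cohort A `cohort_table` (or compatible data frame).
#' @param path CSV file path.
#' @return `path` invisibly; `read_cohort()` returns the data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  if (!is.null(tab$qc_pass)) tab$qc_pass <- as.logical(tab$qc_pass)
  structure(tab, class = c("cohort_table", "data.frame"))
}
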