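#' Progression scenario definitions
#'
#' Four radiographic progression outcome definitions over joint-space
#' narrowing (JSN) grades. Scenarios 1 and 2 evaluate the 24-to-48-month
#' interval (V3 to V6), 3 and 4 the baseline-to-48-month interval (V0 to
#' V6). Scenarios 1 and 3 count an increase in either the medial (JSNM) or
#' lateral (JSNL) grade as progression; scenarios 2 and 4 count medial-only
#' progression (JSNM up, JSNL unchanged) and *exclude* lateral progressors
#' from the dataset rather than labelling them non-progressors.
#'
#' @param id Scenario id, 1--4.
#' @return Object of class `scenario_definition` with fields `id`,
#'   `interval` (`"V3V6"` or `"V0V6"`), `rule` (`"medial_or_lateral"` or
#'   `"medial_only"`).
#' @export
scenario_definition <- function(id) {
  id <- as.integer(id)
  if (!id %in% 1:4) stop("scenario id must be 1, 2, 3 or 4")
  structure(list(id = id,
                 interval = if (id %in% c(1L, 2L)) "V3V6" else "V0V6",
                 rule = if (id %in% c(2L, 4L)) "medial_only"
                        else "medial_or_lateral"),
            class = "scenario_definition")
}

# split a knee's visit rows into a named list keyed by visit
.by_visit <- function(records) {
  setNames(lapply(c("V0", "V3", "V6"),
                  function(v) records[records$visit == v, , drop = FALSE]),
           c("V0", "V3", "V6"))
}

#' Check study inclusion of one knee
#'
#' Eligibility requires a baseline KL grade of 2 or 3 (radiographic entry
#' criterion), complete clinical covariates (age, gender, BMI), WOMAC pain,
#' KL, JSNM and JSNL at V0 and V3, JSNM and JSNL present at V6, and a
#' passing image-quality flag. Always returns a verdict with reason codes
#' enumerating every failed rule.
#'
#' @param records Data frame of the knee's visit rows (V0/V3/V6).
#' @return List with `eligible` (logical) and `reasons` (character vector,
#'   possibly empty; among `kl_entry`, `missing_v0`, `missing_v3`,
#'   `missing_v6`, `qc`).
#' @export
check_inclusion <- function(records) {
  v <- .by_visit(records)
  reasons <- character()
  need <- c("age", "gender", "bmi", "womac_pain", "kl", "jsnm", "jsnl")
  complete_at <- function(row, fields)
    nrow(row) == 1 && !anyNA(row[, fields, drop = TRUE])
  kl0 <- if (nrow(v$V0) == 1) v$V0$kl else NA
  if (is.na(kl0) || !(kl0 %in% c(2, 3))) reasons <- c(reasons, "kl_entry")
  if (!complete_at(v$V0, need)) reasons <- c(reasons, "missing_v0")
  if (!complete_at(v$V3, need)) reasons <- c(reasons, "missing_v3")
  if (!complete_at(v$V6, c("jsnm", "jsnl")))
    reasons <- c(reasons, "missing_v6")
  qc <- records$qc_pass
  if (!is.null(qc) && any(!qc %in% c(TRUE, NA)))
    reasons <- c(reasons, "qc")
  list(eligible = length(reasons) == 0, reasons = reasons)
}

#' Select the index knee of a participant
#'
#' With both knees eligible, the more painful knee (higher baseline WOMAC
#' pain) is the index knee; on a tie, the knee with the *higher* KL grade
#' (the lower-KL knee is excluded); on a further tie, the right knee (left
#' knees are excluded). Deterministic.
#'
#' @param knees Named list of per-knee visit records (`R`, `L`), either may
#'   be missing/ineligible.
#' @param eligible Named logical (`R`, `L`).
#' @return `"R"`, `"L"`, or `NA_character_` when neither knee is eligible
#'   (participant dropped, signalled by the return value, not an error).
#' @export
select_index_knee <- function(knees, eligible) {
  ok <- names(eligible)[eligible]
  if (length(ok) == 0) return(NA_character_)
  if (length(ok) == 1) return(ok)
  womac <- vapply(knees, function(k) k$womac_pain[k$visit == "V0"][1],
                  numeric(1))
  if (womac[["R"]] != womac[["L"]])
    return(if (womac[["R"]] > womac[["L"]]) "R" else "L")
  kl <- vapply(knees, function(k) k$kl[k$visit == "V0"][1], numeric(1))
  if (kl[["R"]] != kl[["L"]])
    return(if (kl[["R"]] > kl[["L"]]) "R" else "L")
  "R"
}

#' Longitudinal delta of a reading
#'
#' Arithmetic difference `value at follow-up minus value at baseline`;
#' `NA` when either side is missing.
#'
#' @param later,baseline Numeric (vectors recycle as usual).
#' @return `later - baseline`.
#' @export
compute_delta <- function(later, baseline) later - baseline

#' Label the progression outcome of one knee under a scenario
#'
#' @param jsnm_start,jsnm_end,jsnl_start,jsnl_end JSN grades at the ends of
#'   the scenario's interval.
#' @param scenario A `scenario_definition`.
#' @return `"progressor"`, `"non_progressor"`, or `"excluded"` (lateral
#'   progressors under the medial-only rule; missing grades).
#' @export
label_outcome <- function(jsnm_start, jsnm_end, jsnl_start, jsnl_end,
                          scenario) {
  stopifnot(inherits(scenario, "scenario_definition"))
  if (anyNA(c(jsnm_start, jsnm_end, jsnl_start, jsnl_end)))
    return("excluded")
  dm <- jsnm_end - jsnm_start
  dl <- jsnl_end - jsnl_start
  if (scenario$rule == "medial_or_lateral") {
    if (dm > 0 || dl > 0) "progressor" else "non_progressor"
  } else {
    if (dl > 0) "excluded"
    else if (dm > 0) "progressor"
    else "non_progressor"
  }
}

#' Exclude early (V0 to V3) JSN progressors from a cohort
#'
#' Removes every knee whose JSNM or JSNL grade increased from baseline to
#' the 24-month visit. The prediction models use 24-month deltas as
#' features, so knees progressing inside the feature window are excluded
#' in all scenarios; [build_analysis_dataset()] applies the same rule to
#' index knees. Knees with a missing V0 or V3 grade are retained here
#' (they fail the completeness rules of [check_inclusion()] instead).
#'
#' @param cohort A `cohort_table` (one row per knee-visit).
#' @return The filtered cohort; attribute `n_removed` counts the excluded
#'   knees.
#' @export
exclude_early_progressors <- function(cohort) {
  key <- paste(cohort$participant_id, cohort$side)
  v0 <- cohort[cohort$visit == "V0", ]
  v3 <- cohort[cohort$visit == "V3", ]
  m <- match(paste(v0$participant_id, v0$side),
             paste(v3$participant_id, v3$side))
  dm <- compute_delta(v3$jsnm[m], v0$jsnm)
  dl <- compute_delta(v3$jsnl[m], v0$jsnl)
  bad <- paste(v0$participant_id, v0$side)[which(dm > 0 | dl > 0)]
  out <- cohort[!key %in% bad, , drop = FALSE]
  attr(out, "n_removed") <- length(bad)
  class(out) <- class(cohort)
  out
}

#' Build the per-scenario analysis dataset
#'
#' Applies the full selection chain to a longitudinal cohort table:
#' knee-level inclusion ([check_inclusion()]), one index knee per
#' participant ([select_index_knee()]), exclusion of early (V0 to V3) JSN
#' progressors, and scenario outcome labelling ([label_outcome()]).
#' Features are baseline covariates, the 64 baseline texture descriptors,
#' their V0-to-V3 deltas, and delta clinical/KL readings.
#'
#' @param cohort A `cohort_table` (one row per knee-visit).
#' @param scenario Scenario id (1--4) or a `scenario_definition`.
#' @return Data frame of class `analysis_dataset`, one row per retained
#'   index knee, with `outcome` in \{0, 1\} and attribute `consort`, a data
#'   frame of stage-by-stage counts.
#' @export
build_analysis_dataset <- function(cohort, scenario) {
  if (!inherits(scenario, "scenario_definition"))
    scenario <- scenario_definition(scenario)
  dn <- intersect(descriptor_names(), colnames(cohort))
  split_pid <- split(seq_len(nrow(cohort)), cohort$participant_id)
  consort <- list(participants = length(split_pid),
                  knees = 0L, knees_eligible = 0L, index_knees = 0L,
                  early_progressor_excluded = 0L,
                  lateral_or_missing_excluded = 0L, final = 0L,
                  progressors = 0L)
  rows <- vector("list", length(split_pid))

  for (i in seq_along(split_pid)) {
    prt <- cohort[split_pid[[i]], , drop = FALSE]
    sides <- intersect(c("R", "L"), unique(prt$side))
    knees <- setNames(lapply(sides, function(s)
      prt[prt$side == s, , drop = FALSE]), sides)
    consort$knees <- consort$knees + length(knees)
    elig <- vapply(knees, function(k) check_inclusion(k)$eligible,
                   logical(1))
    consort$knees_eligible <- consort$knees_eligible + sum(elig)
    side <- select_index_knee(knees, elig)
    if (is.na(side)) next
    consort$index_knees <- consort$index_knees + 1L
    k <- .by_visit(knees[[side]])

    # early-progressor exclusion: any V0->V3 JSN increase
    d_jsnm_03 <- compute_delta(k$V3$jsnm, k$V0$jsnm)
    d_jsnl_03 <- compute_delta(k$V3$jsnl, k$V0$jsnl)
    if (isTRUE(d_jsnm_03 > 0) || isTRUE(d_jsnl_03 > 0)) {
      consort$early_progressor_excluded <-
        consort$early_progressor_excluded + 1L
      next
    }
    start <- if (scenario$interval == "V3V6") k$V3 else k$V0
    lab <- label_outcome(start$jsnm, k$V6$jsnm, start$jsnl, k$V6$jsnl,
                         scenario)
    if (lab == "excluded") {
      consort$lateral_or_missing_excluded <-
        consort$lateral_or_missing_excluded + 1L
      next
    }
    row <- data.frame(
      participant_id = k$V0$participant_id, side = side,
      age = k$V0$age, gender = k$V0$gender, bmi = k$V0$bmi,
      womac_pain = k$V0$womac_pain, kl = k$V0$kl, jsnm = k$V0$jsnm,
      jsnl = k$V0$jsnl,
      delta_bmi = compute_delta(k$V3$bmi, k$V0$bmi),
      delta_womac = compute_delta(k$V3$womac_pain, k$V0$womac_pain),
      delta_kl = compute_delta(k$V3$kl, k$V0$kl),
      outcome = as.integer(lab == "progressor"),
      stringsAsFactors = FALSE)
    if (length(dn)) {
      tbt0 <- as.numeric(k$V0[1, dn])
      tbt3 <- as.numeric(k$V3[1, dn])
      row <- cbind(row,
                   as.data.frame(as.list(setNames(tbt0, dn))),
                   as.data.frame(as.list(setNames(
                     compute_delta(tbt3, tbt0), paste0("d", dn)))))
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0)
    stop("no knees remain after selection; empty analysis dataset")
  consort$final <- nrow(out)
  consort$progressors <- sum(out$outcome)
  rownames(out) <- NULL
  structure(out, class = c("analysis_dataset", "data.frame"),
            consort = data.frame(stage = names(consort),
                                 n = unlist(consort),
                                 row.names = NULL),
            scenario = scenario$id)
}

#' Consort counts of an analysis dataset
#'
#' @param dataset An `analysis_dataset`.
#' @return Data frame of stage-by-stage selection counts.
#' @export
consort_counts <- function(dataset) attr(dataset, "consort")

#' @export
print.analysis_dataset <- function(x, ...) {
  cc <- attr(x, "consort")
  cat(sprintf("<analysis_dataset scenario %d: %d knees, %d progressors (%.1f%%)>\n",
              attr(x, "scenario"), nrow(x), sum(x$outcome),
              100 * mean(x$outcome)))
  print(cc)
  invisible(x)
}
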