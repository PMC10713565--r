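#' The 18-model prediction grid
#'
#' Enumerates the 18 logistic-regression model definitions evaluated by the
#' study. Models 1--5 use baseline clinical covariates (CLIN = age, gender,
#' BMI; CLINW additionally WOMAC pain) and radiographic grades; models 6--18
#' add the texture descriptor blocks (TBT: 64 baseline descriptors; dTBT:
#' their 24-month deltas), which are subject to stepwise-AIC selection,
#' adjusted for forced covariate blocks. Delta JSNM is never a predictor
#' (it is correlated with the outcome by construction).
#'
#' @return List of 18 `model_spec` objects with fields `id`, `label`,
#'   `blocks`, `selectable_blocks`, `forced_blocks`.
#' @export
enumerate_models <- function() {
  grid <- list(
    list(1L,  "CLIN",                          c("CLIN")),
    list(2L,  "CLINW",                         c("CLINW")),
    list(3L,  "CLIN + KL",                     c("CLIN", "KL")),
    list(4L,  "CLIN + JSNM",                   c("CLIN", "JSNM")),
    list(5L,  "CLIN + KL + JSNM",              c("CLIN", "KL", "JSNM")),
    list(6L,  "TBT",                           c("TBT")),
    list(7L,  "TBT + CLIN + KL + JSNM",        c("TBT", "CLIN", "KL", "JSNM")),
    list(8L,  "TBT + dCLIN + KL + JSNM",       c("TBT", "dCLIN", "KL", "JSNM")),
    list(9L,  "TBT + CLIN + dKL + JSNM",       c("TBT", "CLIN", "dKL", "JSNM")),
    list(10L, "TBT + dCLIN + dKL + JSNM",      c("TBT", "dCLIN", "dKL", "JSNM")),
    list(11L, "dTBT + CLIN + KL + JSNM",       c("dTBT", "CLIN", "KL", "JSNM")),
    list(12L, "dTBT + dCLIN + KL + JSNM",      c("dTBT", "dCLIN", "KL", "JSNM")),
    list(13L, "dTBT + CLIN + dKL + JSNM",      c("dTBT", "CLIN", "dKL", "JSNM")),
    list(14L, "dTBT + dCLIN + dKL + JSNM",     c("dTBT", "dCLIN", "dKL", "JSNM")),
    list(15L, "TBT + dTBT + CLIN + KL + JSNM", c("TBT", "dTBT", "CLIN", "KL", "JSNM")),
    list(16L, "TBT + dTBT + dCLIN + KL + JSNM", c("TBT", "dTBT", "dCLIN", "KL", "JSNM")),
    list(17L, "TBT + dTBT + CLIN + dKL + JSNM", c("TBT", "dTBT", "CLIN", "dKL", "JSNM")),
    list(18L, "TBT + dTBT + dCLIN + dKL + JSNM", c("TBT", "dTBT", "dCLIN", "dKL", "JSNM")))
  lapply(grid, function(g) {
    sel <- intersect(g[[3]], c("TBT", "dTBT"))
    structure(list(id = g[[1]], label = g[[2]], blocks = g[[3]],
                   selectable_blocks = sel,
                   forced_blocks = setdiff(g[[3]], sel)),
              class = "model_spec")
  })
}

#' Retrieve one model specification by id
#' @param id Integer 1--18.
#' @return A `model_spec`.
#' @export
model_spec <- function(id) {
  if (!id %in% 1:18) stop("model id must be in 1..18")
  enumerate_models()[[as.integer(id)]]
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model %d: %s\n", x$id, x$label))
  if (length(x$selectable_blocks))
    cat("  selectable (stepwise AIC):",
        paste(x$selectable_blocks, collapse = ", "), "\n")
  invisible(x)
}

# Columns of an analysis dataset belonging to each feature block.
block_columns <- function(block, data, compartments = NULL) {
  dn <- descriptor_names(compartments)
  switch(block,
         CLIN = c("age", "gender_f", "bmi"),
         CLINW = c("age", "gender_f", "bmi", "womac_pain"),
         KL = "kl",
         JSNM = "jsnm",
         dCLIN = "delta_bmi",
         dKL = "delta_kl",
         TBT = intersect(dn, colnames(data)),
         dTBT = intersect(paste0("d", dn), colnames(data)),
         stop("unknown block: ", block))
}

#' Design matrix for a model specification
#'
#' Builds the numeric design matrix (intercept first, then forced blocks,
#' then selectable blocks) from an analysis dataset. Gender is encoded as a
#' binary female indicator; KL and JSN grades enter as numeric scores.
#'
#' @param spec A `model_spec`.
#' @param data An `analysis_dataset` (or compatible data frame).
#' @param compartments Optional compartment subset restricting the texture
#'   ROIs (e.g. `"medial"` for a TBTM sensitivity analysis).
#' @return List with `x` (matrix), `forced`, `selectable` (column-name
#'   vectors; `forced` includes `"(Intercept)"`).
#' @export
model_design <- function(spec, data, compartments = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  df <- as.data.frame(data)
  df$gender_f <- as.numeric(df$gender == "F")
  forced_cols <- unlist(lapply(spec$forced_blocks, block_columns, data = df,
                               compartments = compartments))
  sel_cols <- unlist(lapply(spec$selectable_blocks, block_columns,
                            data = df, compartments = compartments))
  cols <- c(forced_cols, sel_cols)
  x <- cbind("(Intercept)" = 1,
             as.matrix(df[, cols, drop = FALSE]))
  storage.mode(x) <- "double"
  list(x = x, forced = c("(Intercept)", forced_cols),
       selectable = sel_cols %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Standardise non-intercept columns to zero mean / unit sd for the IRLS
# (likelihood, AIC and predictions are invariant; the separation diagnostic
# then acts on per-SD log-odds), and map coefficients back to the raw scale.
column_standard <- function(x) {
  m <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  keep <- !is.finite(s) | s < 1e-12   # intercept / constant columns
  m[keep] <- 0
  s[keep] <- 1
  xs <- sweep(sweep(x, 2, m, "-"), 2, s, "/")
  xs[, keep] <- x[, keep]
  list(x = xs, center = m, scale = s)
}

# raw-scale coefficients from standardised-scale ones; the column named
# "(Intercept)" (if present) absorbs the centering shift
unstandardize_coef <- function(beta_std, center, scale) {
  beta <- beta_std / scale[names(beta_std)]
  int <- which(names(beta) == "(Intercept)")
  if (length(int)) {
    shift <- sum(beta_std[-int] * center[names(beta_std)[-int]] /
                   scale[names(beta_std)[-int]])
    beta[int] <- beta_std[int] - shift
  }
  beta
}

logistic_fit <- function(x, y) {
  std <- column_standard(x)
  fit <- cpp_logistic_fit(std$x, as.numeric(y))
  beta_std <- setNames(as.numeric(fit$coefficients), colnames(x))
  list(coefficients = unstandardize_coef(beta_std, std$center, std$scale),
       loglik = fit$loglik, aic = fit$aic, converged = fit$converged,
       ridged = isTRUE(fit$ridged))
}

#' Stepwise-AIC logistic feature selection
#'
#' Bidirectional stepwise search on the logistic likelihood, starting from
#' the full model (forced plus all selectable columns). Candidate moves are
#' scanned in the order of their estimated AIC change (Wald statistics for
#' drops, Rao score statistics for adds) and the first move whose exact
#' refit strictly lowers `AIC = -2 loglik + 2k` is taken; the search stops
#' only when an exhaustive scan finds no improving single move, i.e. at an
#' AIC local minimum. Forced columns are never dropped. Deterministic given
#' the column order. Quasi-separated fits fall back to a lightly
#' ridge-stabilised solution and are flagged.
#'
#' @param x Numeric design matrix (including an intercept column).
#' @param y Binary 0/1 outcome vector.
#' @param forced Column names always retained.
#' @param selectable Column names subject to selection.
#' @return List with `selected` (column names, forced first),
#'   `coefficients` (named), `aic`, `aic_trace` (strictly decreasing),
#'   `ridged` flag.
#' @export
stepwise_aic <- function(x, y, forced, selectable) {
  stopifnot(is.matrix(x), all(forced %in% colnames(x)),
            all(selectable %in% colnames(x)))
  if (length(unique(y[!is.na(y)])) < 2)
    stop("outcome must contain both classes")
  if (anyNA(x) || anyNA(y)) stop("missing values must be imputed upstream")
  fi <- match(forced, colnames(x)) - 1L
  si <- match(selectable, colnames(x)) - 1L
  std <- column_standard(x)
  res <- cpp_stepwise_aic(std$x, as.numeric(y), as.integer(fi),
                          as.integer(si))
  sel <- colnames(x)[res$selected + 1L]
  coefs <- unstandardize_coef(setNames(as.numeric(res$coefficients), sel),
                              std$center, std$scale)
  list(selected = sel, coefficients = coefs, aic = res$aic,
       loglik = res$loglik, aic_trace = as.numeric(res$aic_trace),
       ridged = isTRUE(res$ridged))
}

#' Fit one progression model
#'
#' Fits the logistic regression of a model specification on an analysis
#' dataset: flagged/missing texture descriptors are mean-imputed, the
#' selectable texture blocks are reduced by [stepwise_aic()] (optional),
#' and the final model is fit by maximum likelihood.
#'
#' @param spec A `model_spec` or model id (1--18).
#' @param data An `analysis_dataset`.
#' @param selection Apply stepwise-AIC selection to the selectable blocks
#'   (default `TRUE`; ignored when the model has none).
#' @param compartments Optional texture-compartment subset.
#' @return Object of class `koa_fit` with `coefficients`, `selected`,
#'   `aic`, `loglik`, and the usual `print`/`summary`/`coef`/`predict`
#'   methods.
#' @export
fit_progression_model <- function(spec, data, selection = TRUE,
                                  compartments = NULL) {
  if (is.numeric(spec)) spec <- model_spec(spec)
  d <- model_design(spec, data, compartments)
  y <- data$outcome
  imp <- impute_columns(d$x)
  x <- imp$x
  if (selection && length(d$selectable)) {
    st <- stepwise_aic(x, y, d$forced, d$selectable)
  } else {
    cols <- c(d$forced, d$selectable)
    fit <- logistic_fit(x[, cols, drop = FALSE], y)
    st <- list(selected = cols, coefficients = fit$coefficients,
               aic = fit$aic, loglik = fit$loglik,
               aic_trace = fit$aic, ridged = fit$ridged)
  }
  structure(list(spec = spec, coefficients = st$coefficients,
                 selected = st$selected, forced = d$forced,
                 selectable = d$selectable, aic = st$aic,
                 loglik = st$loglik, ridged = st$ridged,
                 impute_means = imp$means, n = nrow(x),
                 compartments = compartments),
            class = "koa_fit")
}

# mean-impute NA cells of a design matrix; returns the means used so the
# same imputation can be applied to held-out data (no test information
# flows into training).
impute_columns <- function(x, means = NULL) {
  if (is.null(means)) {
    means <- colMeans(x, na.rm = TRUE)
    means[!is.finite(means)] <- 0
  }
  nas <- which(is.na(x), arr.ind = TRUE)
  if (nrow(nas)) x[nas] <- means[nas[, 2]]
  list(x = x, means = means)
}

#' @export
coef.koa_fit <- function(object, ...) object$coefficients

#' @export
predict.koa_fit <- function(object, newdata, type = c("response", "link"),
                            ...) {
  type <- match.arg(type)
  d <- model_design(object$spec, newdata, object$compartments)
  x <- impute_columns(d$x, object$impute_means)$x
  eta <- drop(x[, object$selected, drop = FALSE] %*% object$coefficients)
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
print.koa_fit <- function(x, ...) {
  cat(sprintf("Logistic progression model (Model %d: %s)\n", x$spec$id,
              x$spec$label))
  cat(sprintf("  n = %d;  AIC = %.2f;  %d of %d selectable features retained%s\n",
              x$n, x$aic,
              length(setdiff(x$selected, x$forced)), length(x$selectable),
              if (x$ridged) " [ridge-stabilised]" else ""))
  invisible(x)
}

#' @export
summary.koa_fit <- function(object, ...) {
  print(object)
  cat("\nCoefficients:\n")
  print(round(object$coefficients, 4))
  invisible(object)
}
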