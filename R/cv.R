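#' Area under the ROC curve
#'
#' Mann--Whitney form: the probability that a random positive scores above
#' a random negative, ties counted one half.
#'
#' @param probabilities Numeric scores.
#' @param labels Binary 0/1 labels (both classes present).
#' @return AUC in [0, 1].
#' @export
auc_mann_whitney <- function(probabilities, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
  r <- rank(probabilities, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics at a probability threshold
#'
#' Balanced accuracy is the arithmetic mean of sensitivity and specificity.
#' PPV (equivalently precision) and NPV are undefined -- returned as `NA`
#' rather than a number -- when no positive (resp. negative) predictions
#' are made.
#'
#' @param probabilities Scores in [0, 1].
#' @param labels Binary 0/1 labels.
#' @param threshold Classification threshold (default 0.5).
#' @return Named list: `auc`, `sensitivity`, `specificity`, `bacc`, `ppv`,
#'   `npv`, `precision`.
#' @export
classification_metrics <- function(probabilities, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  list(auc = auc_mann_whitney(probabilities, labels),
       sensitivity = sens, specificity = spec,
       bacc = mean(c(sens, spec)), ppv = ppv, npv = npv, precision = ppv)
}

# stratified fold assignment: positives and negatives spread separately
stratified_folds <- function(labels, folds) {
  assign <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Repeated stratified cross-validated evaluation of one model
#'
#' Evaluates a model specification by stratified k-fold cross-validation
#' repeated `repeats` times. With `selection = "fold"` (default, leak-free)
#' imputation means and the stepwise-AIC feature subset are recomputed on
#' every training fold; `selection = "pre"` performs a single stepwise
#' selection on the full dataset before cross-validation and folds only
#' refit the selected coefficients -- the published procedure ("before
#' training"), which lets selection see the test folds and is kept for
#' comparability. Out-of-fold probabilities are pooled per repeat; summary
#' metrics are means over repeats and the 95% AUC interval is the
#' 2.5/97.5 percentile of per-repeat AUCs.
#'
#' @param spec A `model_spec` or model id.
#' @param data An `analysis_dataset`.
#' @param folds Number of folds (default 10).
#' @param repeats Number of whole-CV repetitions (study default 300;
#'   reduce for exploratory runs).
#' @param seed Master seed; per-repeat seeds are derived by fixed offsets.
#' @param selection `"fold"`, `"pre"`, or `"none"`.
#' @param compartments Optional texture-compartment subset.
#' @param threshold Classification threshold for BACC/PPV/NPV.
#' @return Object of class `koa_cv`: summary metrics (`auc`, `auc_ci`,
#'   `bacc`, `ppv`, `npv`, `precision`), per-repeat AUCs, mean out-of-fold
#'   probability per sample (`oof`), labels, and the per-feature selection
#'   frequency map.
#' @export
repeated_cv <- function(spec, data, folds = 10L, repeats = 300L, seed = 1L,
                        selection = c("fold", "pre", "none"),
                        compartments = NULL, threshold = 0.5) {
  if (is.numeric(spec)) spec <- model_spec(spec)
  selection <- match.arg(selection)
  y <- data$outcome
  if (sum(y == 1) < folds || sum(y == 0) < folds)
    stop("need at least `folds` knees of each class (have ",
         sum(y == 1), " positives, ", sum(y == 0), " negatives)")
  d <- model_design(spec, data, compartments)
  n <- nrow(d$x)

  pre_selected <- NULL
  if (selection == "pre" && length(d$selectable)) {
    full <- impute_columns(d$x)
    pre_selected <- stepwise_aic(full$x, y, d$forced, d$selectable)$selected
  }
  base_cols <- pre_selected %||% c(d$forced, d$selectable)

  sel_counts <- setNames(numeric(length(d$selectable)), d$selectable)
  n_fits <- 0L
  rep_metrics <- vector("list", repeats)
  oof_sum <- numeric(n)

  for (r in seq_len(repeats)) {
    set.seed(seed + 1000L * r)
    fold_of <- stratified_folds(y, folds)
    oof <- numeric(n)
    for (f in seq_len(folds)) {
      tr <- which(fold_of != f); te <- which(fold_of == f)
      imp <- impute_columns(d$x[tr, , drop = FALSE])
      xte <- impute_columns(d$x[te, , drop = FALSE], imp$means)$x
      if (selection == "fold" && length(d$selectable)) {
        st <- stepwise_aic(imp$x, y[tr], d$forced, d$selectable)
        cols <- st$selected
        beta <- st$coefficients
      } else {
        cols <- base_cols
        beta <- logistic_fit(imp$x[, cols, drop = FALSE],
                             y[tr])$coefficients
      }
      kept <- intersect(cols, d$selectable)
      sel_counts[kept] <- sel_counts[kept] + 1
      n_fits <- n_fits + 1L
      oof[te] <- stats::plogis(
        drop(xte[, cols, drop = FALSE] %*% beta))
    }
    rep_metrics[[r]] <- classification_metrics(oof, y, threshold)
    oof_sum <- oof_sum + oof
  }
  gather <- function(name)
    vapply(rep_metrics, function(m) m[[name]] %||% NA_real_, numeric(1))
  aucs <- gather("auc")
  mean_na <- function(v) if (all(is.na(v))) NA_real_ else
    mean(v, na.rm = TRUE)
  structure(list(
    spec = spec, folds = folds, repeats = repeats, seed = seed,
    selection = selection, n = n, prevalence = mean(y),
    auc = mean(aucs), auc_ci = unname(stats::quantile(
      aucs, c(0.025, 0.975), na.rm = TRUE)),
    bacc = mean_na(gather("bacc")), ppv = mean_na(gather("ppv")),
    npv = mean_na(gather("npv")), precision = mean_na(gather("precision")),
    per_repeat_auc = aucs,
    oof = oof_sum / repeats, labels = y,
    selection_frequency = if (n_fits) sel_counts / n_fits else sel_counts),
    class = "koa_cv")
}

#' @export
print.koa_cv <- function(x, ...) {
  cat(sprintf("Cross-validated Model %d: %s\n", x$spec$id, x$spec$label))
  cat(sprintf("  %d-fold CV x %d repeats (selection: %s), n = %d, prevalence %.3f\n",
              x$folds, x$repeats, x$selection, x$n, x$prevalence))
  cat(sprintf("  AUC %.3f (%.3f-%.3f)  BACC %.3f  PPV %s  NPV %s\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$bacc,
              ifelse(is.na(x$ppv), "NaN", sprintf("%.3f", x$ppv)),
              ifelse(is.na(x$npv), "NaN", sprintf("%.3f", x$npv))))
  invisible(x)
}

#' @export
summary.koa_cv <- function(object, ...) {
  print(object)
  sf <- object$selection_frequency
  if (length(sf)) {
    cat("\nTop selected texture features:\n")
    print(round(sort(sf, decreasing = TRUE)[seq_len(min(8, length(sf)))], 3))
  }
  invisible(object)
}

#' Per-descriptor selection frequency map
#'
#' Fraction of cross-validation training fits in which each texture feature
#' was retained by the stepwise-AIC search, organised by ROI, direction and
#' scale for the baseline (`tbt`) and delta (`dtbt`) blocks.
#'
#' @param cv A `koa_cv`.
#' @return Data frame with columns `feature`, `block`, `roi`, `direction`,
#'   `scale`, `frequency`.
#' @export
selection_frequency_map <- function(cv) {
  stopifnot(inherits(cv, "koa_cv"))
  sf <- cv$selection_frequency
  if (!length(sf))
    return(data.frame(feature = character(), block = character(),
                      roi = integer(), direction = character(),
                      scale = character(), frequency = numeric()))
  feature <- names(sf)
  block <- ifelse(startsWith(feature, "dtbt_"), "dTBT", "TBT")
  core <- sub("^d?tbt_roi", "", feature)
  data.frame(feature = feature, block = block,
             roi = as.integer(substr(core, 1, 2)),
             direction = ifelse(grepl("_h_", feature), "horizontal",
                                "vertical"),
             scale = ifelse(endsWith(feature, "micro"), "micro", "milli"),
             frequency = unname(sf), stringsAsFactors = FALSE)
}

#' @export
plot.koa_cv <- function(x, ...) {
  m <- selection_frequency_map(x)
  if (!nrow(m)) {
    graphics::plot.new()
    graphics::title("no selectable texture features")
    return(invisible(x))
  }
  panels <- split(m, interaction(m$block, m$direction, m$scale, drop = TRUE))
  old <- graphics::par(mfrow = c(ceiling(length(panels) / 4), 4),
                       mar = c(2, 2, 2, 1))
  on.exit(graphics::par(old))
  for (nm in names(panels)) {
    p <- panels[[nm]]
    grid <- matrix(0, 2, 8)
    grid[cbind(p$roi %/% 8 + 1, p$roi %% 8 + 1)] <- p$frequency
    graphics::image(t(grid[2:1, ]), zlim = c(0, 1), axes = FALSE,
                    col = gray.colors(64, start = 1, end = 0), main = nm)
    graphics::box()
  }
  invisible(x)
}

#' Paired comparison of two ROC curves (DeLong)
#'
#' Compares the AUCs of two models evaluated on the same samples with the
#' DeLong placement-value covariance construction for paired curves
#' (two-sided normal test). Accepts either two `koa_cv` objects (their mean
#' out-of-fold probabilities are compared) or two probability vectors plus
#' `labels`.
#'
#' @param a,b `koa_cv` objects or numeric probability vectors.
#' @param labels Binary labels, required when `a` and `b` are vectors.
#' @return Object of class `roc_comparison`: `delta_auc` (AUC(a) -
#'   AUC(b)), `z`, `p_value`, and the two AUCs.
#' @export
compare_roc <- function(a, b, labels = NULL) {
  if (inherits(a, "koa_cv")) {
    if (!identical(a$labels, b$labels))
      stop("the two models were not evaluated on the same samples")
    labels <- a$labels
    pa <- a$oof; pb <- b$oof
    ids <- c(a$spec$id, b$spec$id)
  } else {
    pa <- a; pb <- b
    ids <- c(NA_integer_, NA_integer_)
    if (is.null(labels)) stop("`labels` required with probability vectors")
  }
  if (length(unique(labels)) < 2)
    stop("degenerate labels: both classes required")
  auc_a <- auc_mann_whitney(pa, labels)
  auc_b <- auc_mann_whitney(pb, labels)
  if (isTRUE(all.equal(pa, pb))) {
    z <- 0; p <- 1
  } else {
    ra <- pROC::roc(labels, pa, levels = c(0, 1), direction = "<",
                    quiet = TRUE)
    rb <- pROC::roc(labels, pb, levels = c(0, 1), direction = "<",
                    quiet = TRUE)
    tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    z <- unname(tst$statistic)
    p <- tst$p.value
    if (!is.finite(z)) { z <- 0; p <- 1 }
  }
  structure(list(model_a = ids[1], model_b = ids[2],
                 auc_a = auc_a, auc_b = auc_b,
                 delta_auc = auc_a - auc_b, z = z, p_value = p),
            class = "roc_comparison")
}

#' @export
print.roc_comparison <- function(x, ...) {
  lab <- function(id, auc) if (is.na(id)) sprintf("AUC %.3f", auc)
    else sprintf("Model %d (AUC %.3f)", id, auc)
  cat(sprintf("DeLong paired ROC comparison: %s vs %s\n",
              lab(x$model_a, x$auc_a), lab(x$model_b, x$auc_b)))
  cat(sprintf("  dAUC = %+.4f, z = %.3f, p = %.4g\n", x$delta_auc, x$z,
              x$p_value))
  invisible(x)
}
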