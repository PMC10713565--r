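#' Analysis lag set for the quadratic-variations estimator
#'
#' A named set of strictly increasing integer pixel lags at which mean squared
#' second-order increments are evaluated. Two scales are used by default:
#' `micro` (lags 1--4 px, finest trabecular detail) and `milli` (coarser
#' structure; lags chosen from a physical range in mm when the pixel spacing
#' is known, else 4--16 px).
#'
#' @param name Scale label, conventionally `"micro"` or `"milli"`.
#' @param lags Strictly increasing positive integer lags in pixels.
#' @param range_mm Optional length-2 physical range (mm); with `spacing_mm`
#'   it is converted to pixel lags (4 evenly spaced values, deduplicated).
#' @param spacing_mm Pixel spacing in mm, used only with `range_mm`.
#' @return Object of class `lag_set`.
#' @export
lag_set <- function(name, lags = NULL, range_mm = NULL, spacing_mm = NULL) {
  if (is.null(lags)) {
    if (is.null(range_mm) || is.null(spacing_mm))
      stop("supply `lags`, or `range_mm` together with `spacing_mm`")
    px <- unique(pmax(1L, as.integer(round(
      seq(range_mm[1], range_mm[2], length.out = 4) / spacing_mm + 1e-9))))
    lags <- px
  }
  lags <- as.integer(lags)
  if (length(lags) < 2) stop("a lag set needs at least 2 lags")
  if (any(lags <= 0) || any(diff(lags) <= 0))
    stop("lags must be strictly increasing positive integers")
  structure(list(name = name, lags = lags), class = "lag_set")
}

#' Default micro/milli lag sets
#'
#' @param spacing_mm Pixel spacing in mm; when `NULL` the milli scale falls
#'   back to lags \{4, 8, 12, 16\} px.
#' @return List with elements `micro` and `milli`.
#' @export
default_lag_sets <- function(spacing_mm = NULL) {
  micro <- lag_set("micro", 1:4)
  milli <- if (is.null(spacing_mm)) lag_set("milli", c(4L, 8L, 12L, 16L))
           else lag_set("milli", range_mm = c(0.3, 1.2),
                        spacing_mm = spacing_mm)
  if (length(milli$lags) < 2) milli <- lag_set("milli", c(4L, 8L, 12L, 16L))
  list(micro = micro, milli = milli)
}

#' Mean squared second-order increment of a profile
#'
#' `V(u) = mean over t of (X(t + 2u) - 2 X(t + u) + X(t))^2`. Second-order
#' increments annihilate affine trends, so `V(u)` is exactly 0 for any
#' affine profile, and for fractional Brownian motion `V(u)` scales as
#' `u^(2H)` over the whole range `H` in (0, 1).
#'
#' @param profile Numeric vector, length at least `2 * lag + 1`.
#' @param lag Positive integer lag `u` in samples.
#' @return Non-negative scalar.
#' @export
quadratic_variation <- function(profile, lag) {
  lag <- as.integer(lag)
  n <- length(profile)
  if (lag < 1) stop("`lag` must be a positive integer")
  if (n < 2 * lag + 1)
    stop("profile of length ", n, " too short for lag ", lag,
         " (needs >= ", 2 * lag + 1, ")")
  m <- n - 2 * lag
  d <- profile[(2 * lag + 1):n] - 2 * profile[(lag + 1):(n - lag)] +
    profile[1:m]
  sum(d * d) / m
}

#' Estimate a Hurst exponent by quadratic variations
#'
#' Averages `V(u)` over all supplied profiles at each lag of the lag set,
#' then fits ordinary least squares of `log V-bar(u)` on `log u`; the Hurst
#' estimate is half the slope. Estimates outside (0, 1) are returned as-is
#' but flagged, never clipped; a zero mean quadratic variation at any lag
#' (constant or affine texture) yields a degenerate flag and `NA` estimate.
#'
#' @param profiles A numeric matrix (one profile per row) or list of numeric
#'   vectors.
#' @param lags A `lag_set`, or an integer vector of lags.
#' @param per_profile If `TRUE`, estimate H per profile and average the
#'   estimates instead of averaging `V(u)` first (the default pools `V(u)`
#'   across profiles before the log-log fit, which stabilises the small-lag
#'   variance).
#' @return Object of class `hurst_fit` with elements `h`, `slope`,
#'   `intercept`, `r_squared`, `vbar`, `lags`, `flag` (`"ok"`,
#'   `"out_of_range"` or `"degenerate"`), `n_profiles`.
#' @export
estimate_hurst <- function(profiles, lags, per_profile = FALSE) {
  if (inherits(lags, "lag_set")) lags <- lags$lags
  lags <- as.integer(lags)
  if (is.matrix(profiles)) profiles <- asplit(profiles, 1)
  if (!length(profiles)) stop("need at least one profile")
  min_len <- min(lengths(profiles))
  if (min_len < 2 * max(lags) + 1)
    stop("profiles of length ", min_len, " too short for max lag ",
         max(lags))

  if (per_profile) {
    hs <- vapply(profiles, function(p) {
      f <- estimate_hurst(list(p), lags)
      if (f$flag == "degenerate") NA_real_ else f$h
    }, numeric(1))
    h <- mean(hs, na.rm = TRUE)
    flag <- if (all(is.na(hs))) "degenerate"
            else if (!is.finite(h) || h <= 0 || h >= 1) "out_of_range"
            else "ok"
    return(structure(list(h = if (flag == "degenerate") NA_real_ else h,
                          slope = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, vbar = NULL, lags = lags,
                          flag = flag, n_profiles = length(profiles)),
                     class = "hurst_fit"))
  }

  vmat <- vapply(profiles,
                 function(p) vapply(lags, function(u)
                   quadratic_variation(p, u), numeric(1)),
                 numeric(length(lags)))
  vbar <- if (length(lags) == 1L) mean(vmat) else rowMeans(matrix(
    vmat, nrow = length(lags)))
  flag <- "ok"
  if (any(vbar <= 0)) {
    return(structure(list(h = NA_real_, slope = NA_real_,
                          intercept = NA_real_, r_squared = NA_real_,
                          vbar = vbar, lags = lags, flag = "degenerate",
                          n_profiles = length(profiles)),
                     class = "hurst_fit"))
  }
  x <- log(lags)
  y <- log(vbar)
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2]
  h <- slope / 2
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  if (!is.finite(h) || h <= 0 || h >= 1) flag <- "out_of_range"
  structure(list(h = unname(h), slope = unname(slope),
                 intercept = unname(fit$coefficients[1]),
                 r_squared = r2, vbar = vbar, lags = lags, flag = flag,
                 n_profiles = length(profiles)),
            class = "hurst_fit")
}

#' @export
print.hurst_fit <- function(x, ...) {
  cat("Quadratic-variations Hurst estimate\n")
  cat(sprintf("  H-hat = %s  (flag: %s)\n",
              ifelse(is.na(x$h), "NA", sprintf("%.4f", x$h)), x$flag))
  cat(sprintf("  lags: %s;  profiles: %d", paste(x$lags, collapse = ", "),
              x$n_profiles))
  if (is.finite(x$r_squared)) cat(sprintf(";  R^2 = %.4f", x$r_squared))
  cat("\n")
  invisible(x)
}
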