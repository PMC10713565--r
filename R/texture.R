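#' Specification of a synthetic anisotropic fractal texture
#'
#' @param shape `(rows, cols)` in pixels, both `>= 64`.
#' @param h_horizontal,h_vertical Directional Hurst exponents in (0, 1):
#'   `h_horizontal` governs row profiles (left-right variation),
#'   `h_vertical` column profiles.
#' @param mean_intensity Target mean gray level.
#' @param amplitude Target gray-level standard deviation (> 0).
#' @param spacing_mm Pixel size in mm.
#' @param laterality `"R"` or `"L"`.
#' @param landmarks Optional list with elements `medial` and `lateral`,
#'   each `(x, y)`; defaults place the baseline horizontally at one third
#'   of the image height with a 16-px margin on each side.
#' @param seed Integer RNG seed.
#' @return Object of class `texture_spec`.
#' @export
texture_spec <- function(shape = c(512L, 512L), h_horizontal = 0.5,
                         h_vertical = 0.5, mean_intensity = 0.5,
                         amplitude = 0.1, spacing_mm = 0.2,
                         laterality = "R", landmarks = NULL, seed = 1L) {
  stopifnot(length(shape) == 2)
  if (any(shape < 64)) stop("shape must be at least 64 x 64 pixels")
  for (h in c(h_horizontal, h_vertical))
    if (!is.finite(h) || h <= 0 || h >= 1)
      stop("Hurst exponents must lie strictly in (0, 1)")
  if (amplitude <= 0) stop("amplitude must be > 0")
  structure(list(shape = as.integer(shape), h_horizontal = h_horizontal,
                 h_vertical = h_vertical, mean_intensity = mean_intensity,
                 amplitude = amplitude, spacing_mm = spacing_mm,
                 laterality = laterality, landmarks = landmarks,
                 seed = as.integer(seed)),
            class = "texture_spec")
}

#' Simulate an anisotropic fractal knee-region texture
#'
#' Generates a fractional Brownian *sheet* (separable construction, see
#' [simulate_fbs_field()]): every row profile is an exact fractional
#' Brownian motion with Hurst `h_horizontal` and every column profile one
#' with `h_vertical`, so downstream directional estimates have exact
#' per-direction targets. The field is synthesised with a 32-px buffer and
#' cropped so no degenerate (zero) boundary profiles survive, then affinely
#' mapped to `mean_intensity` +/- `amplitude`. This is a statistical stand-in
#' for radiographic trabecular texture, not a physical bone model.
#'
#' @param spec A `texture_spec`.
#' @return A [knee_image()] carrying the true Hurst exponents in `h_true`.
#' @export
simulate_texture <- function(spec) {
  stopifnot(inherits(spec, "texture_spec"))
  rows <- spec$shape[1]; cols <- spec$shape[2]
  buf <- 32L
  field <- simulate_fbs_field(rows + buf, cols + buf,
                              h_vertical = spec$h_vertical,
                              h_horizontal = spec$h_horizontal,
                              seed = spec$seed)
  field <- field[(buf + 1):(buf + rows), (buf + 1):(buf + cols)]
  field <- (field - mean(field)) / stats::sd(field)
  px <- spec$mean_intensity + spec$amplitude * field

  if (is.null(spec$landmarks)) {
    margin <- 16
    y0 <- floor(rows / 3)
    med <- c(cols - 1 - margin, y0)
    lat <- c(margin, y0)
    if (spec$laterality == "L") { tmp <- med; med <- lat; lat <- tmp }
  } else {
    med <- spec$landmarks$medial
    lat <- spec$landmarks$lateral
  }
  img <- knee_image(px, landmark_medial = med, landmark_lateral = lat,
                    spacing_mm = spec$spacing_mm,
                    laterality = spec$laterality,
                    h_true = c(horizontal = spec$h_horizontal,
                               vertical = spec$h_vertical))
  # fail early if the default grid could not support the default lag sets
  wpx <- sqrt(sum((img$landmark_medial - img$landmark_lateral)^2))
  max_lag <- max(unlist(lapply(default_lag_sets(spec$spacing_mm),
                               `[[`, "lags")))
  if (floor(wpx / 8) < 4 * max_lag)
    stop("image too small: ROI side ", floor(wpx / 8),
         " px cannot support the maximum analysis lag of ", max_lag, " px")
  img
}

#' Write a knee image as 16-bit grayscale TIFF plus JSON sidecar
#'
#' Intensities are clipped to [0, 1] for storage. The sidecar records the
#' landmarks (0-based pixel coordinates, x right / y down), pixel spacing,
#' laterality and, for synthetic images, the true Hurst exponents.
#'
#' @param image A `knee_image`.
#' @param path Output TIFF path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_knee_image <- function(image, path) {
  stopifnot(inherits(image, "knee_image"))
  px <- pmin(pmax(image$pixels, 0), 1)
  tiff::writeTIFF(px, path, bits.per.sample = 16L)
  side <- list(landmark_medial = image$landmark_medial,
               landmark_lateral = image$landmark_lateral,
               spacing_mm = image$spacing_mm,
               laterality = image$laterality,
               qc_pass = image$qc_pass)
  if (!is.null(image$h_true)) side$h_true <- as.list(image$h_true)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a knee image written by [write_knee_image()]
#'
#' @param path TIFF path with a `<path>.json` sidecar next to it.
#' @return A `knee_image`.
#' @export
read_knee_image <- function(path) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  knee_image(px, landmark_medial = side$landmark_medial,
             landmark_lateral = side$landmark_lateral,
             spacing_mm = side$spacing_mm, laterality = side$laterality,
             h_true = if (!is.null(side$h_true)) unlist(side$h_true),
             qc_pass = isTRUE(side$qc_pass))
}

#' Compute the 64 trabecular-bone-texture descriptors of a knee
#'
#' For each of the 16 ROIs, estimates the Hurst exponent of the row profiles
#' (horizontal direction) and the column profiles (vertical direction) at
#' the micro and milli lag sets: 16 x 2 x 2 = 64 descriptors. Degenerate or
#' out-of-range estimates are flagged per entry without aborting the knee.
#'
#' @param image A canonical `knee_image`.
#' @param grid An `roi_grid` from [place_rois()].
#' @param micro,milli `lag_set`s (defaults from [default_lag_sets()] with
#'   the image's pixel spacing).
#' @return Object of class `tbt_descriptors`: a data frame with columns
#'   `roi`, `direction`, `scale`, `h`, `r_squared`, `flag`, `name` (the
#'   cohort CSV column name `tbt_roiNN_<h|v>_<micro|milli>`).
#' @export
compute_descriptors <- function(image, grid, micro = NULL, milli = NULL) {
  stopifnot(inherits(image, "knee_image"), inherits(grid, "roi_grid"))
  if (is.null(micro) || is.null(milli)) {
    ls <- default_lag_sets(image$spacing_mm)
    if (is.null(micro)) micro <- ls$micro
    if (is.null(milli)) milli <- ls$milli
  }
  side <- grid$side[1]
  for (s in list(micro, milli))
    if (max(s$lags) > side / 4)
      stop("max lag ", max(s$lags), " of scale '", s$name,
           "' exceeds ROI side / 4 (= ", side / 4, ")")
  out <- vector("list", 64)
  k <- 0
  for (i in grid$roi) {
    block <- extract_roi_pixels(image, grid, i)
    for (dir in c("horizontal", "vertical")) {
      profiles <- if (dir == "horizontal") block else t(block)
      for (sc in list(micro, milli)) {
        fit <- estimate_hurst(profiles, sc)
        k <- k + 1
        out[[k]] <- data.frame(
          roi = i, direction = dir, scale = sc$name, h = fit$h,
          r_squared = fit$r_squared, flag = fit$flag,
          name = descriptor_name(i, dir, sc$name),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(do.call(rbind, out),
            class = c("tbt_descriptors", "data.frame"))
}

descriptor_name <- function(roi, direction, scale) {
  sprintf("tbt_roi%02d_%s_%s", roi, substr(direction, 1, 1), scale)
}

#' All 64 descriptor column names, in canonical order
#'
#' @param compartments Optional subset of `c("lateral", "central",
#'   "medial")`; restricts the ROIs via the default 8x2 grid layout.
#' @return Character vector of column names.
#' @export
descriptor_names <- function(compartments = NULL) {
  rois <- 0:15
  if (!is.null(compartments)) {
    comp <- c("lateral", "lateral", "lateral", "central", "central",
              "medial", "medial", "medial")[rois %% 8 + 1]
    rois <- rois[comp %in% compartments]
  }
  as.vector(t(outer(rois, c("h_micro", "h_milli", "v_micro", "v_milli"),
                    function(r, s) sprintf("tbt_roi%02d_%s", r, s))))
}
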