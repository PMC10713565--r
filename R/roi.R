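#' Construct a knee image object
#'
#' A grayscale knee-region image with the two proximal-tibia extremity
#' landmarks from which the subchondral ROI grid is placed. Pixel
#' coordinates are 0-based, x to the right, y down; `pixels[r, c]` holds the
#' intensity at x = c - 1, y = r - 1.
#'
#' @param pixels Numeric matrix of intensities.
#' @param landmark_medial,landmark_lateral Numeric `(x, y)` pixel
#'   coordinates of the medial / lateral extremity of the proximal tibia.
#' @param spacing_mm Pixel size in mm (> 0).
#' @param laterality `"L"` or `"R"`.
#' @param h_true Optional named numeric (`horizontal`, `vertical`) ground
#'   truth Hurst exponents, carried by synthetic images.
#' @param qc_pass Logical image-quality flag (defaults `TRUE`).
#' @return Object of class `knee_image`.
#' @export
knee_image <- function(pixels, landmark_medial, landmark_lateral,
                       spacing_mm = 0.2, laterality = c("R", "L"),
                       h_true = NULL, qc_pass = TRUE) {
  laterality <- match.arg(laterality)
  stopifnot(is.matrix(pixels), spacing_mm > 0,
            length(landmark_medial) == 2, length(landmark_lateral) == 2)
  w <- ncol(pixels); h <- nrow(pixels)
  for (lm in list(landmark_medial, landmark_lateral))
    if (lm[1] < 0 || lm[1] > w - 1 || lm[2] < 0 || lm[2] > h - 1)
      stop("landmark (", lm[1], ", ", lm[2], ") outside image bounds")
  if (landmark_medial[1] == landmark_lateral[1])
    stop("landmarks must differ in x")
  structure(list(pixels = pixels,
                 landmark_medial = as.numeric(landmark_medial),
                 landmark_lateral = as.numeric(landmark_lateral),
                 spacing_mm = spacing_mm, laterality = laterality,
                 h_true = h_true, qc_pass = qc_pass,
                 canonical = laterality == "R"),
            class = "knee_image")
}

#' @export
print.knee_image <- function(x, ...) {
  cat(sprintf("<knee_image %dx%d px, %.3g mm/px, %s knee%s>\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing_mm, x$laterality,
              if (x$canonical) ", canonical" else ""))
  invisible(x)
}

# Horizontal mirror: x -> width - 1 - x for pixels and landmarks.
mirror_image <- function(image) {
  w <- ncol(image$pixels)
  image$pixels <- image$pixels[, w:1, drop = FALSE]
  image$landmark_medial[1] <- w - 1 - image$landmark_medial[1]
  image$landmark_lateral[1] <- w - 1 - image$landmark_lateral[1]
  image
}

#' Canonicalize knee orientation
#'
#' Mirrors left-knee images horizontally (remapping landmarks) so that the
#' medial tibial extremity always lies on the same (right-hand) side
#' regardless of laterality; right knees are returned unchanged. Idempotent.
#'
#' @param image A `knee_image`.
#' @return A canonical `knee_image`.
#' @export
canonicalize_orientation <- function(image) {
  stopifnot(inherits(image, "knee_image"))
  if (is.null(image$laterality) || is.na(image$laterality))
    stop("laterality missing; cannot canonicalize")
  if (isTRUE(image$canonical)) return(image)
  image <- mirror_image(image)
  image$canonical <- TRUE
  image
}

# Rotate image about `center` (x, y) by `angle` radians (positive =
# counter-clockwise in the x-right / y-down convention applied to the
# baseline) using bilinear resampling; used to make the inter-landmark
# baseline horizontal before extracting axis-aligned ROIs.
rotate_image_bilinear <- function(pixels, angle, center) {
  h <- nrow(pixels); w <- ncol(pixels)
  xs <- (seq_len(w) - 1) - center[1]
  ys <- (seq_len(h) - 1) - center[2]
  ca <- cos(angle); sa <- sin(angle)
  # output (x, y) samples input (x ca - y sa, x sa + y ca) i.e. inverse map
  gx <- outer(ys * -sa, xs * ca, "+") + center[1]
  gy <- outer(ys * ca, xs * sa, "+") + center[2]
  x0 <- floor(gx); y0 <- floor(gy)
  fx <- gx - x0; fy <- gy - y0
  cl <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  ix0 <- cl(x0, 0, w - 1); ix1 <- cl(x0 + 1, 0, w - 1)
  iy0 <- cl(y0, 0, h - 1); iy1 <- cl(y0 + 1, 0, h - 1)
  at <- function(iy, ix) matrix(pixels[cbind(as.vector(iy) + 1,
                                             as.vector(ix) + 1)],
                                nrow = h)
  out <- (1 - fx) * (1 - fy) * at(iy0, ix0) + fx * (1 - fy) * at(iy0, ix1) +
    (1 - fx) * fy * at(iy1, ix0) + fx * fy * at(iy1, ix1)
  out
}

#' Place the 16-ROI subchondral grid
#'
#' Splits the inter-landmark baseline into 8 equal columns and stacks two
#' rows of square ROIs immediately distal to (below) it, covering the tibial
#' subchondral plateau. On the canonical orientation, columns 0--2 are
#' labelled lateral, 3--4 central and 5--7 medial (6 / 4 / 6 ROIs). When the
#' baseline is not horizontal the image is first rotated about its midpoint
#' (bilinear resampling) so the grid stays axis-aligned with the anatomical
#' horizontal/vertical directions required by the directional estimator.
#'
#' @param image A canonical `knee_image` (see [canonicalize_orientation()]).
#' @param n_cols,n_rows Grid dimensions (defaults 8 x 2 = 16 ROIs).
#' @param lateral_cols,central_cols,medial_cols Column index ranges
#'   (0-based) assigned to each compartment.
#' @param min_side Minimum admissible ROI side in pixels.
#' @param offset_px Vertical gap between baseline and the first ROI row.
#' @return Object of class `roi_grid`: a data frame with one row per ROI
#'   (`roi`, `row_index`, `col_index`, `x0`, `y0`, `side`, `compartment`)
#'   plus attributes `angle` (baseline rotation applied) and `center`.
#' @export
place_rois <- function(image, n_cols = 8L, n_rows = 2L,
                       lateral_cols = 0:2, central_cols = 3:4,
                       medial_cols = 5:7, min_side = 8L, offset_px = 0L) {
  stopifnot(inherits(image, "knee_image"))
  if (!isTRUE(image$canonical))
    stop("image must be in canonical orientation; run ",
         "canonicalize_orientation() first")
  lm_med <- image$landmark_medial
  lm_lat <- image$landmark_lateral
  wpx <- sqrt(sum((lm_med - lm_lat)^2))
  side <- floor(wpx / n_cols)
  if (side < min_side)
    stop("inter-landmark distance ", round(wpx, 1),
         " px too small for ", n_cols, " ROIs of side >= ", min_side, " px")
  angle <- atan2(lm_med[2] - lm_lat[2], lm_med[1] - lm_lat[1])
  center <- (lm_med + lm_lat) / 2
  # landmark positions after rotating the baseline to horizontal
  rot <- function(pt) {
    d <- pt - center
    ca <- cos(-angle); sa <- sin(-angle)
    center + c(ca * d[1] - sa * d[2], sa * d[1] + ca * d[2])
  }
  p_lat <- rot(lm_lat); p_med <- rot(lm_med)
  y0 <- p_lat[2]
  leftover <- wpx - n_cols * side
  x_start <- min(p_lat[1], p_med[1]) + leftover  # margin on the lateral side
  comp <- rep(NA_character_, n_cols)
  comp[lateral_cols + 1] <- "lateral"
  comp[central_cols + 1] <- "central"
  comp[medial_cols + 1] <- "medial"
  g <- expand.grid(col_index = 0:(n_cols - 1), row_index = 0:(n_rows - 1))
  grid <- data.frame(
    roi = seq_len(nrow(g)) - 1L,
    row_index = g$row_index,
    col_index = g$col_index,
    x0 = floor(x_start + g$col_index * side),
    y0 = floor(y0 + offset_px + g$row_index * side),
    side = side,
    compartment = comp[g$col_index + 1],
    stringsAsFactors = FALSE)
  h <- nrow(image$pixels); w <- ncol(image$pixels)
  bad <- which(grid$x0 < 0 | grid$y0 < 0 | grid$x0 + side > w |
                 grid$y0 + side > h)
  if (length(bad))
    stop("ROIs out of image bounds: ",
         paste(grid$roi[bad], collapse = ", "))
  structure(grid, class = c("roi_grid", "data.frame"),
            angle = angle, center = center, n_cols = n_cols,
            n_rows = n_rows)
}

#' Extract the pixel block of one ROI
#'
#' Returns the square intensity sub-grid of ROI `index`. No intensity
#' preprocessing is applied. If the grid was placed on a rotated baseline,
#' the same rotation is applied to the image before extraction.
#'
#' @param image The `knee_image` the grid was placed on.
#' @param grid An `roi_grid`.
#' @param index ROI index, 0--15.
#' @return `side x side` numeric matrix.
#' @export
extract_roi_pixels <- function(image, grid, index) {
  stopifnot(inherits(grid, "roi_grid"))
  if (!(index %in% grid$roi)) stop("ROI index ", index, " out of range")
  px <- image$pixels
  angle <- attr(grid, "angle")
  if (abs(angle) > 1e-9)
    px <- rotate_image_bilinear(px, angle, attr(grid, "center"))
  r <- grid[grid$roi == index, ]
  px[(r$y0 + 1):(r$y0 + r$side), (r$x0 + 1):(r$x0 + r$side), drop = FALSE]
}

#' Serialize an ROI grid to JSON
#'
#' @param grid An `roi_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_roi_grid <- function(grid, path) {
  jsonlite::write_json(
    list(angle = attr(grid, "angle"),
         rois = as.data.frame(grid)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
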