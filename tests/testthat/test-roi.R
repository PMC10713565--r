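test_that("canonicalization mirrors left knees and is idempotent", {
  r <- flat_knee_image(laterality = "R")
  expect_identical(canonicalize_orientation(r), r)

  set.seed(2)
  px <- matrix(runif(400 * 800), 400, 800)
  l <- knee_image(px, landmark_medial = c(10, 100),
                  landmark_lateral = c(790, 100), laterality = "L")
  lc <- canonicalize_orientation(l)
  expect_equal(lc$landmark_medial[1], 800 - 1 - 10)
  expect_true(lc$canonical)
  expect_identical(canonicalize_orientation(lc), lc)
  # mirroring is an involution on pixels
  expect_equal(tbtprog:::mirror_image(tbtprog:::mirror_image(l))$pixels, px)
  l$laterality <- NA
  expect_error(canonicalize_orientation(l), "laterality")
})

test_that("knee_image validates landmarks and spacing", {
  expect_error(knee_image(matrix(0, 10, 10), c(20, 5), c(1, 5)),
               "outside image bounds")
  expect_error(knee_image(matrix(0, 10, 10), c(5, 5), c(5, 2)),
               "differ in x")
  expect_error(knee_image(matrix(0, 10, 10), c(5, 5), c(1, 5),
                          spacing_mm = 0), "spacing_mm")
})

test_that("horizontal-baseline grid matches the stated layout exactly", {
  img <- knee_image(matrix(0.5, 400, 801), landmark_medial = c(800, 100),
                    landmark_lateral = c(0, 100))
  g <- place_rois(img)
  expect_equal(nrow(g), 16)
  expect_true(all(g$side == 100))
  expect_equal(sort(unique(g$y0)), c(100, 200))      # rows at y in [100,300)
  expect_equal(sort(g$x0[g$row_index == 0]), seq(0, 700, by = 100))
  expect_equal(as.vector(table(g$compartment)[c("lateral", "central",
                                                "medial")]),
               c(6L, 4L, 6L))
  # medial columns on the right (canonical orientation)
  expect_true(min(g$x0[g$compartment == "medial"]) >
                max(g$x0[g$compartment == "lateral"]))
  expect_identical(g, place_rois(img))  # deterministic
})

test_that("ROIs never overlap and cover the inter-landmark width", {
  img <- knee_image(matrix(0.5, 300, 650), landmark_medial = c(633, 60),
                    landmark_lateral = c(7, 60))
  g <- place_rois(img)
  # pairwise non-overlap via exclusive pixel ownership
  occ <- matrix(0L, 300, 650)
  for (i in seq_len(nrow(g))) {
    rr <- (g$y0[i] + 1):(g$y0[i] + g$side[i])
    cc <- (g$x0[i] + 1):(g$x0[i] + g$side[i])
    occ[rr, cc] <- occ[rr, cc] + 1L
  }
  expect_lte(max(occ), 1L)
  width_covered <- 8 * g$side[1]
  expect_gte(width_covered / (633 - 7), 0.95)
})

test_that("grid placement fails loudly when it cannot fit", {
  img <- knee_image(matrix(0.5, 64, 200), landmark_medial = c(60, 10),
                    landmark_lateral = c(20, 10))
  expect_error(place_rois(img), "too small")
  low <- knee_image(matrix(0.5, 150, 801), landmark_medial = c(800, 100),
                    landmark_lateral = c(0, 100))
  expect_error(place_rois(low), "out of image bounds")
  nc <- flat_knee_image(laterality = "L")
  expect_error(place_rois(nc), "canonical")
})

test_that("rotated baselines are handled by rotation-corrected extraction", {
  set.seed(5)
  base <- simulate_fbs_field(560, 560, 0.5, 0.5, seed = 5)
  img <- knee_image(base, landmark_medial = c(500, 120),
                    landmark_lateral = c(60, 80))  # ~5 degree baseline
  g <- place_rois(img)
  expect_equal(nrow(g), 16)
  px <- extract_roi_pixels(img, g, 0)
  expect_equal(dim(px), c(g$side[1], g$side[1]))
  expect_gt(attr(g, "angle"), 0)
})

test_that("compartment labels are independent of laterality", {
  set.seed(11)
  px <- matrix(runif(400 * 820), 400, 820)
  right <- knee_image(px, landmark_medial = c(810, 100),
                      landmark_lateral = c(10, 100), laterality = "R")
  left <- knee_image(px[, 820:1], landmark_medial = c(820 - 1 - 810, 100),
                     landmark_lateral = c(820 - 1 - 10, 100),
                     laterality = "L")
  gr <- place_rois(canonicalize_orientation(right))
  gl <- place_rois(canonicalize_orientation(left))
  expect_identical(gr$compartment, gl$compartment)
  expect_identical(extract_roi_pixels(canonicalize_orientation(right), gr, 3),
                   extract_roi_pixels(canonicalize_orientation(left), gl, 3))
})

test_that("extract_roi_pixels returns raw unpreprocessed blocks", {
  img <- knee_image(matrix(7.5, 400, 801), landmark_medial = c(800, 100),
                    landmark_lateral = c(0, 100))
  g <- place_rois(img)
  blk <- extract_roi_pixels(img, g, 5)
  expect_true(all(blk == 7.5))
  expect_equal(dim(blk), c(100, 100))
  expect_error(extract_roi_pixels(img, g, 16), "out of range")
  expect_lte(sum(g$side^2), length(img$pixels))
})
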