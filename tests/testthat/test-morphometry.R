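test_that("ellipse measurements match the analytic axes and area", {
  # semi-axes 20 mm x 8 mm at 10 px/mm
  r <- render_silhouette(data.frame(span_mm = 40, chord_mm = 16),
                         scale = 10, wing_fraction = 0)
  m <- measure_silhouette(r$silhouette)
  expect_equal(m$span_mm, 40, tolerance = 0.2 / 40)
  expect_equal(m$chord_mm, 16, tolerance = 0.2 / 16)
  expect_equal(m$area_cm2, pi * 20 * 8 / 100, tolerance = 0.02)
})

test_that("rectangle span is the diagonal and chord its conjugate width", {
  # 30 mm x 10 mm rectangle at 10 px/mm; oracle over the corner pixels
  sil <- as_sil(matrix(1L, 100, 300), scale = 0.1)
  m <- measure_silhouette(sil)
  expect_equal(m$span_mm, sqrt(30^2 + 10^2), tolerance = 0.2 / 31.6)
  expect_equal(m$chord_mm, 2 * 30 * 10 / sqrt(30^2 + 10^2),
               tolerance = 0.2 / 18.97)
  expect_equal(m$area_cm2, 3, tolerance = 0.01)
  # projection oracle from the corner pixel centers
  corners <- rbind(c(0.5, 0.5), c(0.5, 299.5), c(99.5, 0.5),
                   c(99.5, 299.5)) # (row, col)
  u <- c(299, 99) / sqrt(299^2 + 99^2) # measured span direction (col, row)
  pr <- corners[, 2] * -u[2] + corners[, 1] * u[1]
  expect_equal(m$chord_mm, (max(pr) - min(pr)) * 0.1, tolerance = 1e-10)
})

test_that("a disk measures its diameter in span and chord", {
  n <- 201
  xy <- expand.grid(r = 1:n, c = 1:n)
  mask <- matrix(0L, n, n)
  mask[(xy$r - 101)^2 + (xy$c - 101)^2 <= 100^2] <- 1L
  sil <- as_sil(mask, scale = 0.1)
  m <- measure_silhouette(sil)
  expect_equal(m$span_mm, 20, tolerance = 0.2 / 20)
  expect_equal(m$chord_mm, 20, tolerance = 0.2 / 20)
  expect_equal(m$area_cm2, pi * 10^2 / 100, tolerance = 0.02)
})

test_that("hull-based span equals brute force over all pixel pairs", {
  set.seed(41)
  for (i in 1:8) {
    mask <- matrix(as.integer(runif(30 * 30) > 0.7), 30, 30)
    if (!sum(mask)) next
    sil <- as_sil(mask, scale = 0.25)
    expect_identical(measure_span(sil)$span_mm, brute_span(sil))
  }
  r <- render_silhouette(data.frame(span_mm = 20, chord_mm = 7), scale = 5)
  expect_identical(measure_span(r$silhouette)$span_mm,
                   brute_span(r$silhouette))
})

test_that("chord never exceeds span and area fits the bounding box", {
  set.seed(42)
  shapes <- list(
    render_silhouette(data.frame(span_mm = 25, chord_mm = 8),
                      scale = 6)$silhouette,
    render_silhouette(data.frame(span_mm = 40, chord_mm = 14), scale = 6,
                      wing_fraction = 0)$silhouette,
    as_sil(matrix(as.integer(runif(900) > 0.6), 30, 30), scale = 0.3))
  for (sil in shapes) {
    m <- measure_silhouette(sil)
    expect_lte(m$chord_mm, m$span_mm)
    expect_lte(m$area_cm2 * 100, m$span_mm * m$chord_mm)
  }
})

test_that("measurements are rotation-invariant to within discretisation", {
  base <- render_silhouette(data.frame(span_mm = 35, chord_mm = 11),
                            scale = 10)
  m0 <- measure_silhouette(base$silhouette)
  for (ang in c(17, 63, 118)) {
    r <- render_silhouette(data.frame(span_mm = 35, chord_mm = 11),
                           scale = 10, angle_deg = ang)
    m <- measure_silhouette(r$silhouette)
    expect_lt(abs(m$span_mm / m0$span_mm - 1), 0.02)
    expect_lt(abs(m$chord_mm / m0$chord_mm - 1), 0.02)
    expect_lt(abs(m$area_cm2 / m0$area_cm2 - 1), 0.02)
  }
})

test_that("segmentation recovers the rendered mask and its pixel count", {
  r <- render_silhouette(data.frame(span_mm = 30, chord_mm = 10), scale = 8)
  img <- 1 - r$silhouette$mask # dark shape on white
  s <- segment_silhouette(img, scale = 1 / 8)
  expect_equal(sum(s$mask), r$truth$pixel_count)
  # inverted polarity gives the identical mask
  s_inv <- segment_silhouette(1 - img, scale = 1 / 8, polarity = "light")
  expect_identical(s$mask, s_inv$mask)
})

test_that("segmentation keeps the largest component and fills holes", {
  img <- matrix(1, 80, 120)
  img[20:60, 10:60] <- 0    # large blob
  img[30:45, 35:45] <- 1    # hole inside it -> must be filled
  img[10:15, 100:110] <- 0  # small distractor blob
  s <- segment_silhouette(img, scale = 0.1)
  expect_equal(sum(s$mask), 41 * 51) # hole refilled, distractor dropped
  expect_equal(sum(s$mask[10:15, 100:110]), 0)
})

test_that("uniform images fail segmentation naming the threshold", {
  expect_error(segment_silhouette(matrix(0.5, 40, 40), scale = 0.1),
               "segmentation failure.*threshold")
  # explicit threshold override is honoured
  img <- matrix(1, 50, 50); img[10:40, 10:40] <- 0.4
  s <- segment_silhouette(img, scale = 0.1, threshold = 0.5)
  expect_equal(sum(s$mask), 31 * 31)
})

test_that("degenerate collinear silhouettes report a one-pixel chord", {
  mask <- matrix(0L, 5, 60)
  mask[3, 5:55] <- 1L
  sil <- as_sil(mask, scale = 0.2)
  expect_warning(ch <- measure_chord(sil), "degenerate")
  expect_equal(ch, 0.2)
})

test_that("span endpoints are 0-based and tie-broken deterministically", {
  r <- render_silhouette(data.frame(span_mm = 30, chord_mm = 12),
                         scale = 5, wing_fraction = 0)
  sp <- measure_span(r$silhouette)
  ep <- sp$endpoints
  expect_true(all(ep >= 0))
  expect_true(all(ep[, 1] < nrow(r$silhouette$mask)))
  expect_true(all(ep[, 2] < ncol(r$silhouette$mask)))
  expect_gt(abs(ep[1, 2] - ep[2, 2]), 140)
  # rectangle: both diagonals tie exactly; the lexicographically smallest
  # (row, col) pair must win
  sp_r <- measure_span(as_sil(matrix(1L, 50, 120), scale = 0.1))
  expect_equal(sp_r$endpoints, matrix(c(0L, 0L, 49L, 119L), 2L,
                                      byrow = TRUE))
})

test_that("silhouette PNG files round-trip through the reader", {
  tmp <- withr::local_tempdir()
  r <- render_silhouette(data.frame(span_mm = 24, chord_mm = 8), scale = 6)
  f <- file.path(tmp, "spec.png")
  write_silhouette_png(r, f)
  img <- read_silhouette(f)
  s <- segment_silhouette(img, scale = 1 / 6)
  expect_equal(sum(s$mask), r$truth$pixel_count)
})
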