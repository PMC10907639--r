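# EBImage's bwlabel is 4-connected; merge labels that touch diagonally to
# obtain 8-connected components (union-find over the label graph).
.label8 <- function(mask) {
  lab4 <- EBImage::bwlabel(EBImage::Image(t(mask)))
  lab <- t(EBImage::imageData(lab4))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))   # down-left
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  lab[lab > 0] <- root[lab[lab > 0]]
  lab
}

#' Segment a samara silhouette from a greyscale photograph
#'
#' Thresholds a tabletop photograph (dark samara on a light background by
#' default), keeps the largest 8-connected foreground component, and fills
#' interior holes. The threshold defaults to Otsu's method; pass
#' `threshold` to override. For light-on-dark imagery set
#' `polarity = "light"`.
#'
#' @param image numeric matrix (row-major, values in \[0, 1\], row 1 =
#'   top) or an `EBImage` Image; see [read_silhouette()].
#' @param scale mm per pixel (> 0), attached to the result.
#' @param threshold optional scalar in (0, 1); default Otsu.
#' @param polarity `"dark"` (foreground darker than background, default)
#'   or `"light"`.
#' @param min_px minimum plausible component size (default 50 px).
#' @return A `silhouette` object: list with binary row-major `mask` and
#'   `scale` (mm/px).
#' @examples
#' r <- render_silhouette(data.frame(span_mm = 25, chord_mm = 9), scale = 5)
#' img <- 1 - r$silhouette$mask  # dark shape on white
#' s <- segment_silhouette(img, scale = 1 / 5)
#' sum(s$mask) == r$truth$pixel_count
#' @export
segment_silhouette <- function(image, scale, threshold = NULL,
                               polarity = c("dark", "light"),
                               min_px = 50) {
  polarity <- match.arg(polarity)
  if (inherits(image, "Image")) {
    if (EBImage::colorMode(image) != 0) {
      image <- EBImage::channel(image, "gray")
    }
    image <- t(EBImage::imageData(image))
    if (length(dim(image)) > 2L) image <- image[, , 1L]
  }
  stopifnot(is.matrix(image), length(image) > 0)
  if (polarity == "light") image <- 1 - image
  if (is.null(threshold)) {
    threshold <- tryCatch(
      EBImage::otsu(EBImage::Image(t(image))),
      error = function(e) NA_real_)
  }
  fg <- if (is.na(threshold)) matrix(FALSE, nrow(image), ncol(image)) else
    image < threshold
  lab <- if (any(fg)) .label8(fg * 1L) else fg * 1L
  sizes <- if (max(lab) > 0) tabulate(lab[lab > 0]) else integer(0)
  if (!length(sizes) || max(sizes) < min_px) {
    stop("segmentation failure: no connected component with >= ", min_px,
         " px at threshold ", format(threshold), call. = FALSE)
  }
  best <- which.max(sizes)
  mask <- (lab == best) * 1L
  filled <- EBImage::fillHull(EBImage::Image(t(mask)))
  mask <- t(EBImage::imageData(filled))
  structure(list(mask = mask, scale = scale), class = "silhouette")
}

#' Read an image file for silhouette analysis
#'
#' Thin wrapper over `EBImage::readImage` (PNG/TIFF/JPEG) returning a
#' row-major greyscale matrix in \[0, 1\].
#'
#' @param file image path.
#' @return numeric matrix, row 1 = top of the image.
#' @export
read_silhouette <- function(file) {
  img <- EBImage::readImage(file)
  if (EBImage::colorMode(img) != 0) img <- EBImage::channel(img, "gray")
  m <- EBImage::imageData(img)
  if (length(dim(m)) > 2L) m <- m[, , 1L]
  t(m)
}

# foreground pixel centers in mm, x right / y down from the top-left corner
.fg_points_mm <- function(s) {
  idx <- which(s$mask == 1L, arr.ind = TRUE)
  cbind(x = (idx[, "col"] - 0.5) * s$scale,
        y = (idx[, "row"] - 0.5) * s$scale)
}

.check_silhouette <- function(s) {
  stopifnot(inherits(s, "silhouette"), is.matrix(s$mask), s$scale > 0)
  if (sum(s$mask) < 1L) stop("empty silhouette", call. = FALSE)
  invisible(s)
}

#' Measure span: the longest dimension of the silhouette
#'
#' The span is the maximum Euclidean distance between any two foreground
#' pixel centers, found on the convex hull (whose diameter provably equals
#' the brute-force maximum over all pixel pairs). Among exactly tied
#' pairs, the lexicographically smallest (row, col) pair is reported, so
#' the measurement is deterministic on symmetric shapes.
#'
#' @param s a `silhouette`.
#' @return list with `span_mm` and `endpoints` (2 x 2 matrix of 0-based
#'   (row, col) pixel indices).
#' @examples
#' r <- render_silhouette(data.frame(span_mm = 30, chord_mm = 10), scale = 5)
#' measure_span(r$silhouette)$span_mm
#' @export
measure_span <- function(s) {
  .check_silhouette(s)
  idx <- which(s$mask == 1L, arr.ind = TRUE)
  pts <- cbind(idx[, "col"], idx[, "row"]) # pixel units
  h <- if (nrow(pts) > 2L) grDevices::chull(pts) else seq_len(nrow(pts))
  hp <- pts[h, , drop = FALSE]
  d2 <- as.matrix(stats::dist(hp))^2
  dmax2 <- max(d2)
  cand <- which(d2 == dmax2, arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  if (!nrow(cand)) cand <- matrix(c(1L, 1L), 1L) # single pixel
  # order each pair's endpoints, then pick the lexicographically smallest
  key <- t(apply(cand, 1L, function(ij) {
    a <- c(hp[ij[1], 2], hp[ij[1], 1]); b <- c(hp[ij[2], 2], hp[ij[2], 1])
    if (a[1] > b[1] || (a[1] == b[1] && a[2] > b[2])) c(b, a) else c(a, b)
  }))
  best <- do.call(order, as.data.frame(key))[1L]
  ep <- matrix(key[best, ], 2L, byrow = TRUE) # (row, col) 1-based
  list(span_mm = sqrt(dmax2) * s$scale,
       endpoints = ep - 1L) # 0-based, origin top-left
}

#' Measure chord: maximum extent perpendicular to the span line
#'
#' Projects every foreground pixel center onto the direction
#' perpendicular to the span-defining pair and reports the extent
#' (max - min) in mm. Degenerate (collinear) silhouettes report one
#' pixel-equivalent with a warning.
#'
#' @param s a `silhouette`.
#' @param span optional result of [measure_span()] (recomputed if
#'   missing).
#' @return chord in mm.
#' @export
measure_chord <- function(s, span = NULL) {
  .check_silhouette(s)
  if (is.null(span)) span <- measure_span(s)
  ep <- span$endpoints + 1L
  u <- c(ep[2L, 2L] - ep[1L, 2L], ep[2L, 1L] - ep[1L, 1L]) # (dx, dy)
  nu <- sqrt(sum(u^2))
  if (nu == 0) {
    warning("degenerate silhouette: single-pixel span")
    return(1 * s$scale)
  }
  u <- u / nu
  idx <- which(s$mask == 1L, arr.ind = TRUE)
  pr <- idx[, "col"] * (-u[2L]) + idx[, "row"] * u[1L]
  # perpendicular extent never exceeds the diameter; clamp fp noise
  extent <- min((max(pr) - min(pr)) * s$scale, span$span_mm)
  if (extent == 0) {
    warning("degenerate (collinear) silhouette: chord floor of one pixel")
    return(1 * s$scale)
  }
  extent
}

#' Measure plan area from the foreground pixel count
#'
#' @param s a `silhouette`.
#' @return area in cm^2 (`count * scale^2 / 100`).
#' @export
measure_area <- function(s) {
  .check_silhouette(s)
  sum(s$mask) * s$scale^2 / 100
}

#' Measure span, chord and area of a silhouette in one call
#'
#' @param s a `silhouette`.
#' @return list with `span_mm`, `chord_mm`, `area_cm2`, `endpoints`
#'   (0-based span endpoints), `pixel_count`.
#' @examples
#' r <- render_silhouette(data.frame(span_mm = 30, chord_mm = 10), scale = 5)
#' measure_silhouette(r$silhouette)
#' @export
measure_silhouette <- function(s) {
  sp <- measure_span(s)
  list(span_mm = sp$span_mm,
       chord_mm = measure_chord(s, span = sp),
       area_cm2 = measure_area(s),
       endpoints = sp$endpoints,
       pixel_count = sum(s$mask))
}
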