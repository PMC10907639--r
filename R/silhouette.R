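# quadratic Bezier sampled at t in [0,1]
.bezier2 <- function(p0, c1, p2, n = 120) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1] + 2 * t * (1 - t) * c1[1] + t^2 * p2[1],
        (1 - t)^2 * p0[2] + 2 * t * (1 - t) * c1[2] + t^2 * p2[2])
}

#' Parametric samara outline polygon
#'
#' Builds a closed plan-view outline in mm: a nutlet (ellipse arc) at the
#' origin end joined to a tapered wing whose leading edge is a quadratic
#' Bezier curve and whose trailing edge is straight. With
#' `wing_fraction = 0` the outline degenerates to a pure ellipse with
#' major axis `span_mm` and minor axis `chord_mm`.
#'
#' @param span_mm overall length along the long axis, mm.
#' @param chord_mm approximate transverse extent, mm.
#' @param wing_fraction fraction of the span occupied by the wing
#'   (default 0.62; 0 gives the ellipse).
#' @param n_arc points on the nutlet/ellipse arc.
#' @return Two-column matrix of (x, y) vertices in mm, closed implicitly.
#' @export
samara_outline <- function(span_mm, chord_mm, wing_fraction = 0.62,
                           n_arc = 360) {
  stopifnot(span_mm > 0, chord_mm > 0, chord_mm <= span_mm,
            wing_fraction >= 0, wing_fraction < 1)
  if (wing_fraction == 0) {
    phi <- seq(0, 2 * pi, length.out = n_arc + 1L)[-(n_arc + 1L)]
    return(cbind(span_mm / 2 * cos(phi), chord_mm / 2 * sin(phi)))
  }
  x_j <- (1 - wing_fraction) * span_mm   # nutlet extent along x
  a <- x_j / 2
  b <- 0.30 * chord_mm                    # nutlet half-height
  cx <- a
  phi <- seq(deg2rad(75), deg2rad(285), length.out = n_arc)
  nutlet <- cbind(cx + a * cos(phi), b * sin(phi))
  tip <- c(span_mm, 0)
  # wing: broad mid-wing section carrying both transverse extremes (the
  # curved leading edge above, the sagging trailing edge below), tapering
  # to a tip on the nutlet axis
  x_m <- x_j + 0.5 * (span_mm - x_j)
  top0 <- nutlet[1L, ]      # nutlet top-right, ~ +0.97 b
  bot0 <- nutlet[n_arc, ]   # nutlet bottom-right, ~ -0.97 b
  c_top <- c(x_m, 2 * (0.62 * chord_mm - (tip[2] + top0[2]) / 4))
  c_bot <- c(x_m, -2 * (0.38 * chord_mm + (bot0[2] + tip[2]) / 4))
  trailing <- .bezier2(bot0, c_bot, tip, n = 100)
  leading <- .bezier2(tip, c_top, top0, n = 120)
  rbind(nutlet, trailing[-1, , drop = FALSE],
        leading[-c(1, 120), , drop = FALSE])
}

# shoelace area of a closed polygon (vertices not repeated)
.polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  j <- c(seq_len(nrow(p))[-1L], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# diameter (max pairwise distance) of a point set via its convex hull,
# with the realising pair
.hull_diameter <- function(p) {
  h <- grDevices::chull(p)
  hp <- p[h, , drop = FALSE]
  d2 <- as.matrix(stats::dist(hp))^2
  ij <- which(d2 == max(d2), arr.ind = TRUE)[1L, ]
  list(diameter = sqrt(max(d2)), p1 = hp[ij[1L], ], p2 = hp[ij[2L], ])
}

# width of a point set perpendicular to the unit direction u
.perp_extent <- function(p, u) {
  perp <- c(-u[2L], u[1L])
  pr <- p %*% perp
  max(pr) - min(pr)
}

#' Render a silhouette raster with analytic ground truth
#'
#' Rasterises a [samara_outline()] at the requested resolution by an
#' even-odd point-in-polygon test at pixel centers, and returns the mask
#' together with ground truth computed by exact geometry on the outline
#' polygon: span (convex-hull diameter), chord (extent perpendicular to
#' the span direction), area (shoelace), and the rendered foreground
#' pixel count. The render is a pure function of its arguments, so a
#' repeated call is bit-identical.
#'
#' @param morphology single-row data.frame with `span_mm` and `chord_mm`
#'   (e.g. a row of a generated morphology table).
#' @param scale resolution in px/mm (>= 5).
#' @param wing_fraction see [samara_outline()]; 0 renders a plain ellipse.
#' @param angle_deg rotate the outline by this angle before rasterising
#'   (the ground truth is rotation-invariant by construction).
#' @param margin_mm blank border around the shape.
#' @param max_px refuse to allocate a canvas larger than this many pixels.
#' @return list of class `silhouette_render`: `silhouette` (a `silhouette`
#'   object: binary row-major `mask`, `scale` in mm/px), `truth` (list
#'   `span_mm`, `chord_mm`, `area_cm2`, `pixel_count`), and `outline`.
#' @examples
#' r <- render_silhouette(data.frame(span_mm = 30, chord_mm = 10),
#'                        scale = 5)
#' r$truth$span_mm
#' @export
render_silhouette <- function(morphology, scale = 10, wing_fraction = 0.62,
                              angle_deg = 0, margin_mm = 2, max_px = 4e6) {
  stopifnot(is.data.frame(morphology), nrow(morphology) == 1L,
            all(c("span_mm", "chord_mm") %in% names(morphology)))
  if (scale < 5) stop("scale must be >= 5 px/mm", call. = FALSE)
  poly <- samara_outline(morphology$span_mm, morphology$chord_mm,
                         wing_fraction = wing_fraction)
  if (angle_deg != 0) {
    th <- deg2rad(angle_deg)
    poly <- poly %*% matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L)
  }
  xr <- range(poly[, 1]) + c(-margin_mm, margin_mm)
  yr <- range(poly[, 2]) + c(-margin_mm, margin_mm)
  ncol_px <- ceiling(diff(xr) * scale)
  nrow_px <- ceiling(diff(yr) * scale)
  if (ncol_px * nrow_px > max_px) {
    stop("canvas too small a budget: needs ", ncol_px, " x ", nrow_px,
         " px (> max_px = ", max_px, ")", call. = FALSE)
  }
  px <- (rep(seq_len(ncol_px), each = nrow_px) - 0.5) / scale + xr[1]
  py <- (yr[2] - (rep(seq_len(nrow_px), times = ncol_px) - 0.5) / scale)
  inside <- rep(FALSE, length(px))
  nv <- nrow(poly)
  jx <- poly[c(nv, seq_len(nv - 1L)), 1]
  jy <- poly[c(nv, seq_len(nv - 1L)), 2]
  for (k in seq_len(nv)) {
    x1 <- poly[k, 1]; y1 <- poly[k, 2]; x2 <- jx[k]; y2 <- jy[k]
    if (y1 == y2) next
    cross <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, cross)
  }
  mask <- matrix(as.integer(inside), nrow = nrow_px, ncol = ncol_px)
  hd <- .hull_diameter(poly)
  u <- (hd$p2 - hd$p1) / hd$diameter
  structure(list(
    silhouette = structure(list(mask = mask, scale = 1 / scale),
                           class = "silhouette"),
    truth = list(span_mm = hd$diameter,
                 chord_mm = .perp_extent(poly, u),
                 area_cm2 = .polygon_area(poly) / 100,
                 pixel_count = sum(mask)),
    outline = poly
  ), class = "silhouette_render")
}

#' @export
print.silhouette_render <- function(x, ...) {
  cat(sprintf(
    "Rendered silhouette: %d x %d px at %.3g mm/px, %d foreground px\n",
    nrow(x$silhouette$mask), ncol(x$silhouette$mask), x$silhouette$scale,
    x$truth$pixel_count))
  cat(sprintf("  ground truth: span %.2f mm, chord %.2f mm, area %.3f cm^2\n",
              x$truth$span_mm, x$truth$chord_mm, x$truth$area_cm2))
  invisible(x)
}

#' Write a silhouette mask as a PNG (dark shape on white)
#'
#' @param silhouette a `silhouette` object (or `silhouette_render`).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_silhouette_png <- function(silhouette, file) {
  if (inherits(silhouette, "silhouette_render")) {
    silhouette <- silhouette$silhouette
  }
  png::writePNG(1 - silhouette$mask, file)
  invisible(file)
}
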