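# Semi-automated healing of knife-tear artifacts: midline estimation from
# paired control points ("stitches"), bisection of the section, and
# per-half rigid-MLS warping of the tear edges onto the midline.

#' Estimate the tear midline from stitch annotations
#'
#' Interpolates the midpoints of the annotated pairs and projects the ends
#' (linear extrapolation from the terminal segments) to the image border,
#' producing a path that divides the section into exactly two pieces. The
#' path must be monotone along one image axis (the dominant axis of the
#' midpoint spread, chosen automatically).
#'
#' @param pairs list with `a`, `b`: N x 2 matrices of paired control points
#'   (0-based px) straddling the tear.
#' @param shape c(h, w) of the image.
#' @return list of class `tear_midline`: `axis` ("y" or "x"), `f(t)` path
#'   function (position of the midline at coordinate t along the axis),
#'   `midpoints`, `side(x, y)` returning -1/+1.
#' @export
estimate_midline <- function(pairs, shape) {
  a <- matrix(pairs$a, ncol = 2); b <- matrix(pairs$b, ncol = 2)
  stopifnot(nrow(a) == nrow(b), nrow(a) >= 2)
  mid <- (a + b) / 2
  axis <- if (diff(range(mid[, 2])) >= diff(range(mid[, 1]))) "y" else "x"
  t_ <- if (axis == "y") mid[, 2] else mid[, 1]
  v_ <- if (axis == "y") mid[, 1] else mid[, 2]
  o <- order(t_)
  t_ <- t_[o]; v_ <- v_[o]
  if (any(duplicated(t_))) { keep <- !duplicated(t_); t_ <- t_[keep]; v_ <- v_[keep] }
  if (length(t_) < 2) stop("stitch midpoints are degenerate along the tear axis")
  n <- length(t_)
  tmax <- (if (axis == "y") shape[1] else shape[2]) - 1
  slope0 <- (v_[2] - v_[1]) / (t_[2] - t_[1])
  slope1 <- (v_[n] - v_[n - 1]) / (t_[n] - t_[n - 1])
  f <- function(t) {
    out <- stats::approx(t_, v_, xout = t, rule = 2)$y
    lo <- t < t_[1]; hi <- t > t_[n]
    out[lo] <- v_[1] + slope0 * (t[lo] - t_[1])
    out[hi] <- v_[n] + slope1 * (t[hi] - t_[n])
    out
  }
  vmax <- (if (axis == "y") shape[2] else shape[1]) - 1
  ends <- f(c(0, tmax))
  if (any(!is.finite(ends)))
    stop("midline fails to reach the image border")
  side <- function(x, y) {
    if (axis == "y") sign(x - f(y) + 1e-12) else sign(y - f(x) + 1e-12)
  }
  structure(list(axis = axis, f = f, midpoints = cbind(ifelse(axis == "y", 1, 0)),
                 mid_t = t_, mid_v = v_, side = side, shape = shape),
            class = "tear_midline")
}

# interpolators for the two tear edges, parameterized by the midline axis
edge_interp <- function(pts, axis) {
  t_ <- if (axis == "y") pts[, 2] else pts[, 1]
  v_ <- if (axis == "y") pts[, 1] else pts[, 2]
  o <- order(t_); t_ <- t_[o]; v_ <- v_[o]
  keep <- !duplicated(t_); t_ <- t_[keep]; v_ <- v_[keep]
  function(t) stats::approx(t_, v_, xout = t, rule = 2)$y
}

#' Heal a torn section
#'
#' Estimates the midline, splits the image into the two halves on either
#' side of it, and warps each half independently with rigid MLS so that the
#' interpolated tear-edge control points land on the interpolated midline
#' points (shared arclength parameterization along the tear). Warping each
#' half separately avoids presenting the MLS model with the discontinuity.
#' The deformation is confined to a band around the tear (displacements are
#' blended to identity between `band_inner_px` and `band_outer_px`), so the
#' far field is untouched.
#'
#' @param image torn section image.
#' @param pairs stitch annotation (see [estimate_midline()]).
#' @param stitch_spacing_px spacing of interpolated control points along the
#'   tear.
#' @param band_inner_px,band_outer_px deformation confinement band.
#' @param config [pipeline_config()] (MLS alpha).
#' @return list: `image` (healed), `midline`, `gap_mask` (pixels near the
#'   midline still unfilled).
#' @export
heal_tear <- function(image, pairs, stitch_spacing_px = 12,
                      band_inner_px = 40, band_outer_px = 96,
                      config = pipeline_config()) {
  h <- nrow(image); w <- ncol(image)
  ml <- estimate_midline(pairs, c(h, w))
  axis <- ml$axis
  a <- matrix(pairs$a, ncol = 2); b <- matrix(pairs$b, ncol = 2)
  # put a on the negative side, b on the positive side
  sa <- ml$side(a[, 1], a[, 2]); sb <- ml$side(b[, 1], b[, 2])
  coincident <- rowSums((a - b)^2) < 1e-12   # zero-opening stitches
  sa[coincident] <- -1; sb[coincident] <- 1
  if (any(sa == sb))
    stop("control-point pair does not straddle the estimated midline")
  neg <- rbind(a[sa < 0, , drop = FALSE], b[sb < 0, , drop = FALSE])
  pos <- rbind(a[sa > 0, , drop = FALSE], b[sb > 0, , drop = FALSE])
  if (!nrow(neg) || !nrow(pos)) stop("degenerate half: no control points on one side")
  tmax <- (if (axis == "y") h else w) - 1
  ts <- seq(min(ml$mid_t), max(ml$mid_t), by = stitch_spacing_px)
  if (length(ts) < 2) ts <- range(ml$mid_t)
  mid_v <- ml$f(ts)
  fneg <- edge_interp(neg, axis); fpos <- edge_interp(pos, axis)
  to_xy <- function(t, v) if (axis == "y") cbind(v, t) else cbind(t, v)
  ctrl_mid <- to_xy(ts, mid_v)
  ctrl_neg <- to_xy(ts, fneg(ts))
  ctrl_pos <- to_xy(ts, fpos(ts))
  g <- coord_grid(h, w)
  qx <- as.vector(g$x); qy <- as.vector(g$y)
  sgn <- ml$side(qx, qy)
  # perpendicular-ish distance to the midline along the off-axis direction
  dist <- if (axis == "y") abs(qx - ml$f(qy)) else abs(qy - ml$f(qx))
  blend <- pmin(pmax((band_outer_px - dist) / (band_outer_px - band_inner_px), 0), 1)
  map_x <- matrix(qx, h, w); map_y <- matrix(qy, h, w)
  for (s in c(-1, 1)) {
    ctrl_dst_space <- ctrl_mid                       # healed coordinates
    ctrl_src_space <- if (s < 0) ctrl_neg else ctrl_pos  # torn coordinates
    sel <- which(sgn == s & blend > 0)
    if (!length(sel)) next
    src <- mls_rigid(ctrl_dst_space, ctrl_src_space,
                     cbind(qx[sel], qy[sel]), alpha = config$mls_alpha)
    bx <- blend[sel]
    map_x[sel] <- qx[sel] + bx * (src[, 1] - qx[sel])
    map_y[sel] <- qy[sel] + bx * (src[, 2] - qy[sel])
  }
  # keep each half's lookups on its own side of the tear in the torn image:
  # source points that crossed the (displaced) edge would sample the gap
  rm <- remap_image(image, map_x, map_y, fill = 0)
  healed <- rm$image
  gap <- healed == 0 & matrix(dist, h, w) <= band_inner_px
  list(image = healed, midline = ml, gap_mask = gap)
}
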