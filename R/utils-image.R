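# Image containers are plain numeric matrices m[row, col] with gray values in
# [0, 255]. Public pixel coordinates are 0-based pixel centers: x = col - 1
# (rightward), y = row - 1 (downward). Physical coordinates are nm:
# xy_nm = xy_px * pixel_size_nm.

#' Bilinear sampling of an image at fractional pixel coordinates
#'
#' @param img numeric matrix (rows = y, cols = x).
#' @param x,y numeric vectors of 0-based pixel coordinates.
#' @param fill value returned for samples outside the image (default `NA`).
#' @return numeric vector of sampled intensities.
#' @export
bilinear_sample <- function(img, x, y, fill = NA_real_) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  # clamp so that edge pixels (x == w-1) sample exactly
  at_xedge <- x0 >= w - 1 & x <= w - 1 + 1e-9
  at_yedge <- y0 >= h - 1 & y <= h - 1 + 1e-9
  x0[at_xedge] <- w - 2; fx[at_xedge] <- 1
  y0[at_yedge] <- h - 2; fy[at_yedge] <- 1
  ok <- x0 >= 0 & y0 >= 0 & x0 <= w - 2 & y0 <= h - 2 &
    is.finite(x) & is.finite(y)
  out <- rep(fill, length(x))
  if (!any(ok)) return(out)
  x0k <- x0[ok]; y0k <- y0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
  i00 <- (x0k) * h + y0k + 1          # [y0+1, x0+1] in column-major order
  v00 <- img[i00];       v10 <- img[i00 + h]
  v01 <- img[i00 + 1];   v11 <- img[i00 + h + 1]
  out[ok] <- (1 - fyk) * ((1 - fxk) * v00 + fxk * v10) +
    fyk * ((1 - fxk) * v01 + fxk * v11)
  out
}

#' Remap an image through a destination-to-source coordinate lookup
#'
#' For every destination pixel `(x, y)` the output takes the bilinearly
#' interpolated source intensity at `(map_x[y, x], map_y[y, x])`.
#'
#' @param img source image matrix.
#' @param map_x,map_y matrices (destination shape) of 0-based source pixel
#'   coordinates.
#' @param fill intensity for destination pixels mapping outside the source.
#' @return list with `image` (matrix) and `mask` (logical matrix, TRUE where
#'   the lookup fell inside the source).
#' @export
remap_image <- function(img, map_x, map_y, fill = 0) {
  stopifnot(all(dim(map_x) == dim(map_y)))
  v <- bilinear_sample(img, as.vector(map_x), as.vector(map_y), fill = NA_real_)
  mask <- !is.na(v)
  v[!mask] <- fill
  list(image = matrix(v, nrow(map_x), ncol(map_x)),
       mask = matrix(mask, nrow(map_x), ncol(map_x)))
}

#' 0-based pixel-center coordinate grids for an h x w image
#' @param h,w image dimensions.
#' @return list of matrices `x`, `y` of dim (h, w).
#' @export
coord_grid <- function(h, w) {
  list(x = matrix(rep(0:(w - 1), each = h), h, w),
       y = matrix(rep(0:(h - 1), times = w), h, w))
}

#' Rotate an image about its center
#'
#' Destination pixel (x, y) samples the source at the position obtained by
#' rotating (x, y) by `-angle_deg` about the image center, so features of the
#' output appear rotated counter-clockwise by `angle_deg` in pixel axes
#' (y down).
#'
#' @param img image matrix.
#' @param angle_deg rotation angle in degrees.
#' @param fill fill value outside the source.
#' @return image matrix of identical size.
#' @export
rotate_image <- function(img, angle_deg, fill = 0) {
  if (angle_deg == 0) return(img)
  h <- nrow(img); w <- ncol(img)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  th <- -angle_deg * pi / 180
  g <- coord_grid(h, w)
  dx <- g$x - cx; dy <- g$y - cy
  sx <- cx + cos(th) * dx - sin(th) * dy
  sy <- cy + sin(th) * dx + cos(th) * dy
  remap_image(img, sx, sy, fill = fill)$image
}

#' Block-mean downsampling
#'
#' @param img image matrix.
#' @param factor integer block size; trailing rows/cols that do not fill a
#'   block are dropped.
#' @return downsampled matrix of block means.
#' @export
block_reduce <- function(img, factor, fun = mean) {
  factor <- as.integer(factor)
  if (factor <= 1) return(img)
  h <- (nrow(img) %/% factor) * factor
  w <- (ncol(img) %/% factor) * factor
  img <- img[seq_len(h), seq_len(w), drop = FALSE]
  a <- array(img, c(factor, h %/% factor, factor, w %/% factor))
  apply(a, c(2, 4), fun)
}

# box filter by running sums with replicate edge normalization (kernel
# truncated at the borders); size in pixels, forced odd
box_filter <- function(img, size) {
  size <- max(1L, as.integer(size))
  if (size %% 2L == 0L) size <- size + 1L
  if (size == 1L) return(img)
  r <- (size - 1L) %/% 2L
  sum1d <- function(m, r) {
    n <- nrow(m)
    cs <- rbind(0, apply(m, 2, cumsum))
    hi <- pmin(seq_len(n) + r, n) + 1L
    lo <- pmax(seq_len(n) - r, 1L)
    cnt <- hi - lo
    (cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]) / cnt
  }
  t(sum1d(t(sum1d(img, r)), r))
}

#' 256-bin histogram of an 8-bit image (values clamped to \[0,255\])
#' @param img image matrix.
#' @return integer vector of 256 counts.
#' @export
hist256 <- function(img) {
  v <- as.integer(round(pmin(pmax(as.vector(img), 0), 255)))
  tabulate(v + 1L, nbins = 256L)
}

# histogram mode on a lightly smoothed 256-bin histogram (stabilizes the
# estimate on small/averaged samples); ties broken toward the lower intensity
hist_mode <- function(img, smooth = 5L) {
  h <- hist256(img)
  if (smooth > 1L) h <- stats::filter(h, rep(1 / smooth, smooth), sides = 2)
  which.max(h) - 1L
}

#' Clamp intensities to the 8-bit range
#' @param img image matrix.
#' @export
clamp255 <- function(img) pmin(pmax(img, 0), 255)

#' Write / read a grayscale 8-bit PNG image
#'
#' Intensities are rounded and clamped to \[0, 255\].
#' @param img image matrix in \[0, 255\].
#' @param path file path.
#' @export
write_gray_png <- function(img, path) {
  png::writePNG(clamp255(round(img)) / 255, target = path)
  invisible(path)
}

#' @rdname write_gray_png
#' @export
read_gray_png <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  round(a * 255)
}
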