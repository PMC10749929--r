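# Preprocessing and normalized cross-correlation (nxcorr) template matching.
# Correlation is computed in the frequency domain and normalized in the
# spatial domain using precomputed image integrals; peak localization is
# integer-pixel at the working pixel size.

log_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  xs <- -r:r
  g <- exp(-xs^2 / (2 * sigma^2))
  G <- outer(g, g)
  X2 <- outer(xs^2, rep(1, length(xs))); Y2 <- t(X2)
  K <- G * (X2 + Y2 - 2 * sigma^2) / sigma^4
  K <- K / sum(G)
  K - mean(K)                      # zero-DC so flat regions respond with 0
}

#' Preprocess an image for normalized cross-correlation
#'
#' Applies the matching preprocessing chain: contrast-limited adaptive
#' histogram equalization (CLAHE, clip limit 30 with 32 x 32 px tiles at a
#' 16 nm pixel size), conversion to float, whitening with a
#' Laplacian-of-Gaussian filter (sigma 4 px at 16 nm), and zero-normalization
#' (subtract the mean, divide by the standard deviation scaled by the square
#' root of the pixel count, so the output has zero mean and unit total
#' energy). CLAHE tile size and LoG sigma scale inversely with the pixel
#' size.
#'
#' Images whose raw grayscale variance falls below the configured floor are
#' flagged invalid instead of being normalized.
#'
#' @param img 8-bit grayscale matrix.
#' @param pixel_size_nm pixel size of `img` in nm.
#' @param config [pipeline_config()].
#' @return list: `image` (float matrix), `valid` (logical low-variance flag).
#' @export
preprocess_image <- function(img, pixel_size_nm = 16, config = pipeline_config()) {
  stopifnot(length(img) > 0)
  if (stats::var(as.vector(img)) < config$variance_floor)
    return(list(image = img * 0, valid = FALSE))
  scale <- 16 / pixel_size_nm
  tile <- max(2L, round(config$clahe_tile_px * scale))
  nx <- max(2L, round(ncol(img) / tile))
  ny <- max(2L, round(nrow(img) / tile))
  x <- t(img) / 255                      # EBImage uses (x, y) storage
  # config states the clip limit on the absolute (OpenCV-style) scale;
  # EBImage's clahe() uses the Zuiderveld normalized scale, about a tenth
  x <- tryCatch(
    EBImage::clahe(EBImage::Image(x), nx = nx, ny = ny,
                   limit = config$clahe_clip / 10),
    error = function(e) x)
  x <- t(as.matrix(x)) * 255
  sigma <- max(0.6, config$log_sigma_px * scale)
  K <- log_kernel(sigma)
  x <- t(as.matrix(EBImage::filter2(EBImage::Image(t(x)), K, boundary = "replicate")))
  x <- x - mean(x)
  ss <- sqrt(sum(x^2))
  if (ss < 1e-12) return(list(image = x * 0, valid = FALSE))
  list(image = x / ss, valid = TRUE)
}

# 2D integral-image local sums of all h x w windows of m (valid positions)
local_sums <- function(m, h, w) {
  H <- nrow(m); W <- ncol(m)
  S <- matrix(0, H + 1, W + 1)
  S[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  ys <- 1:(H - h + 1); xs <- 1:(W - w + 1)
  S[ys + h, xs + w, drop = FALSE] - S[ys, xs + w, drop = FALSE] -
    S[ys + h, xs, drop = FALSE] + S[ys, xs, drop = FALSE]
}

# frequency-domain cross-correlation of image with template (valid positions)
fft_xcorr <- function(img, tmpl) {
  H <- nrow(img); W <- ncol(img); h <- nrow(tmpl); w <- ncol(tmpl)
  Tp <- matrix(0, H, W)
  Tp[1:h, 1:w] <- tmpl
  cc <- Re(stats::fft(stats::fft(img) * Conj(stats::fft(Tp)), inverse = TRUE)) / (H * W)
  cc[1:(H - h + 1), 1:(W - w + 1), drop = FALSE]
}

#' Normalized cross-correlation template matching
#'
#' Slides `template` over `image` and reports the integer-pixel location of
#' the highest zero-normalized correlation. The correlation numerator is
#' computed in the frequency domain; per-window normalization uses integral
#' images of the main image. The reported delta is the displacement of the
#' template center at its best position relative to the main image center
#' (pixel centers, 0-based; for even dimensions centers fall on half pixels),
#' converted to nm. Ties in the correlation surface are broken by the
#' smallest y, then smallest x.
#'
#' In `"valid"` mode the template must lie fully inside the image; in
#' `"full"` mode the template may hang off the image borders (the image is
#' zero-padded and each window is normalized over the padded window, so
#' partial-overlap matches such as inter-mFOV tile comparisons are scored),
#' subject to a minimum overlap fraction of the template area.
#'
#' @param img main image (float matrix, typically preprocessed).
#' @param template template, strictly smaller than `img` in both axes.
#' @param pixel_size_nm pixel size for the delta (default 16).
#' @param mode `"valid"` or `"full"` (see above).
#' @param min_overlap_frac minimum in-image fraction of the template for a
#'   `"full"`-mode position to be considered.
#' @return list of class `match_result`: `delta_nm`, `delta_px`,
#'   `peak_value`, `best_angle_deg` (0 here), `valid`.
#' @export
nxcorr_match <- function(img, template, pixel_size_nm = 16,
                         mode = c("valid", "full"), min_overlap_frac = 0.25) {
  mode <- match.arg(mode)
  H <- nrow(img); W <- ncol(img); h <- nrow(template); w <- ncol(template)
  if (h >= H || w >= W) stop("template must be strictly smaller than the image")
  invalid <- list(delta_nm = c(NA_real_, NA_real_), delta_px = c(NA_real_, NA_real_),
                  peak_value = NA_real_, best_angle_deg = 0, valid = FALSE)
  tv <- stats::var(as.vector(template))
  if (!is.finite(tv) || tv < 1e-20) return(structure(invalid, class = "match_result"))
  T0 <- template - mean(template)
  tnorm <- sqrt(sum(T0^2))
  n <- h * w
  if (mode == "full") {
    P <- matrix(0, H + 2 * (h - 1), W + 2 * (w - 1))
    P[h - 1 + seq_len(H), w - 1 + seq_len(W)] <- img
    Pm <- matrix(0, nrow(P), ncol(P))
    Pm[h - 1 + seq_len(H), w - 1 + seq_len(W)] <- 1
    num <- fft_xcorr(P, T0)
    s1 <- local_sums(P, h, w)
    s2 <- local_sums(P^2, h, w)
    cnt <- local_sums(Pm, h, w)
    off <- c(w - 1, h - 1)                # 0-based top-left = index-1 - off
  } else {
    num <- fft_xcorr(img, T0)
    s1 <- local_sums(img, h, w)
    s2 <- local_sums(img^2, h, w)
    cnt <- NULL
    off <- c(0, 0)
  }
  den2 <- pmax(s2 - s1^2 / n, 0)
  den <- sqrt(den2) * tnorm
  ok <- den > 1e-12 * max(den, 1e-300)
  if (!is.null(cnt)) ok <- ok & cnt >= min_overlap_frac * n
  if (!any(ok)) return(structure(invalid, class = "match_result"))
  cc <- num / pmax(den, 1e-300)
  cc[!ok] <- -Inf
  best <- max(cc)
  hits <- which(cc >= best - 1e-12, arr.ind = TRUE)
  pick <- unname(hits[order(hits[, 1], hits[, 2])[1], ])  # smallest y, then x
  py0 <- pick[1] - 1 - off[2]; px0 <- pick[2] - 1 - off[1]
  dpx <- c(px0 + (w - 1) / 2 - (W - 1) / 2,
           py0 + (h - 1) / 2 - (H - 1) / 2)
  structure(list(delta_nm = dpx * pixel_size_nm, delta_px = dpx,
                 peak_value = min(max(best, -1 - 1e-6), 1 + 1e-6),
                 best_angle_deg = 0, valid = TRUE),
            class = "match_result")
}

# centered crop removing `margin` pixels on each side
crop_margin <- function(m, margin) {
  if (margin <= 0) return(m)
  h <- nrow(m); w <- ncol(m)
  if (2 * margin >= h - 1 || 2 * margin >= w - 1)
    stop("rotation margin consumes the whole template")
  m[(margin + 1):(h - margin), (margin + 1):(w - margin), drop = FALSE]
}

#' nxcorr matching with a template rotation sweep
#'
#' Rotates the template about its center by every angle in `angles_deg`
#' (borders cropped symmetrically to the valid interior, preserving the
#' center convention), matches each, and returns the result with the highest
#' correlation peak. A reported `best_angle_deg` of `+a` means the template
#' content had to be rotated by `+a` (counter-clockwise in pixel axes) to
#' best match the main image.
#'
#' @inheritParams nxcorr_match
#' @param angles_deg non-empty numeric vector of sweep angles.
#' @return `match_result` with `best_angle_deg` set.
#' @export
nxcorr_match_rotated <- function(img, template, angles_deg = seq(-15, 15, by = 3),
                                 pixel_size_nm = 16, mode = "valid",
                                 min_overlap_frac = 0.25) {
  stopifnot(length(angles_deg) > 0)
  best <- NULL
  for (a in angles_deg) {
    tm <- if (a == 0) template else {
      margin <- ceiling(abs(sin(a * pi / 180)) * max(dim(template)) / 2) + 1L
      crop_margin(rotate_image(template, a, fill = 0), margin)
    }
    r <- tryCatch(nxcorr_match(img, tm, pixel_size_nm, mode = mode,
                               min_overlap_frac = min_overlap_frac),
                  error = function(e) NULL)
    if (is.null(r) || !r$valid) next
    if (is.null(best) || r$peak_value > best$peak_value) {
      r$best_angle_deg <- a
      best <- r
    }
  }
  if (is.null(best))
    best <- structure(list(delta_nm = c(NA_real_, NA_real_),
                           delta_px = c(NA_real_, NA_real_),
                           peak_value = NA_real_, best_angle_deg = NA_real_,
                           valid = FALSE), class = "match_result")
  best
}
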