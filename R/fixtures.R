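# Ground-truth fixture generation: EM-like phantom textures, hexagonal tile
# layouts with planted acquisition artifacts, section stacks with known
# rigid/elastic deformations, and tears. All randomness flows through the
# seed recorded in the returned bundle, and all planted ground truth is
# returned alongside the data.

#' Generate an EM-like phantom texture
#'
#' Band-limited Gaussian noise thresholded into membrane-like dark ridges,
#' overlaid on low-frequency "cell body" regions with little texture, so
#' fixtures contain both nxcorr-friendly structure and realistic
#' low-structure areas that exercise the outlier paths.
#'
#' @param h,w size in pixels.
#' @param seed integer seed.
#' @param cell_frac fraction of area covered by low-texture cell bodies.
#' @return matrix in \[0, 255\].
#' @export
fixture_phantom <- function(h, w, seed = 1, cell_frac = 0.15) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  pad <- 8L
  n <- matrix(stats::rnorm((h + 2 * pad) * (w + 2 * pad)), h + 2 * pad, w + 2 * pad)
  sm <- box_filter(box_filter(n, 3), 3)
  sm <- sm[pad + seq_len(h), pad + seq_len(w)]
  sm <- sm / stats::sd(sm)
  ridges <- abs(sm) < 0.3                   # membrane skeleton
  # moderate texture amplitude keeps the histogram peaked around the
  # neuropil gray, as in real EM data
  base <- 150 + 50 * sm
  base[ridges] <- 40                        # dark membranes
  lf <- matrix(stats::rnorm((h %/% 24 + 3) * (w %/% 24 + 3)), h %/% 24 + 3, w %/% 24 + 3)
  g <- coord_grid(h, w)
  lfv <- bilinear_sample(lf, g$x / 24 + 1, g$y / 24 + 1, fill = 0)
  cells <- matrix(lfv, h, w) > stats::quantile(lfv, 1 - cell_frac)
  base[cells] <- 190                        # bright low-texture cell bodies
  fine <- matrix(stats::rnorm(h * w, sd = 6), h, w)
  # soften edges to the ~2-3 px acutance of real EM data at 16 nm
  clamp255(round(box_filter(base + fine, 3)))
}

#' Hexagonal mFOV beam layout
#'
#' Beam positions on a hexagonal lattice in rings around a center beam
#' (1 ring = 7 beams, 4 rings = 61, 5 rings = 91 as in production). The
#' lattice center spacing is `tile_w_nm - intra_overlap_nm`, with rows
#' spaced by `sqrt(3)/2` of it.
#'
#' @param n_rings number of hexagonal rings.
#' @param tile_shape_px c(height, width) of a tile in pixels.
#' @param pixel_size_nm pixel size.
#' @param intra_overlap_nm nominal overlap between horizontally adjacent
#'   tiles in an mFOV.
#' @param inter_overlap_nm nominal overlap between adjacent mFOVs.
#' @return list of class `mfov_layout`: `beam_xy` (B x 2 nm, beam 1 at the
#'   center), `spacing_nm`, `tile_shape_px`, `pixel_size_nm`, overlaps and
#'   the mFOV superlattice spacing `mfov_spacing_nm`.
#' @export
hex_layout <- function(n_rings = 1, tile_shape_px = c(112, 128), pixel_size_nm = 16,
                       intra_overlap_nm = NULL, inter_overlap_nm = NULL) {
  tw <- tile_shape_px[2] * pixel_size_nm
  th <- tile_shape_px[1] * pixel_size_nm
  if (is.null(intra_overlap_nm)) intra_overlap_nm <- round(0.15 * tw)
  if (is.null(inter_overlap_nm)) inter_overlap_nm <- round(0.25 * tw)
  s <- tw - intra_overlap_nm
  if (s <= 0) stop("infeasible geometry: intra overlap >= tile width")
  if (th <= s * sqrt(3) / 2) stop("infeasible geometry: tiles too short for hex rows")
  ax <- list()
  for (a in -n_rings:n_rings) for (b in -n_rings:n_rings)
    if (abs(a + b) <= n_rings) ax[[length(ax) + 1]] <- c(a, b)
  ax <- do.call(rbind, ax)
  # center beam first, then by ring
  ring <- pmax(abs(ax[, 1]), abs(ax[, 2]), abs(ax[, 1] + ax[, 2]))
  ax <- ax[order(ring, ax[, 1], ax[, 2]), , drop = FALSE]
  xy <- cbind(s * (ax[, 1] + ax[, 2] / 2), s * ax[, 2] * sqrt(3) / 2)
  width <- (2 * n_rings + 1) * s
  structure(list(beam_xy = xy, spacing_nm = s, tile_shape_px = tile_shape_px,
                 pixel_size_nm = pixel_size_nm,
                 intra_overlap_nm = intra_overlap_nm,
                 inter_overlap_nm = inter_overlap_nm,
                 mfov_spacing_nm = width - inter_overlap_nm),
            class = "mfov_layout")
}

# centers (nm) of mFOVs at hex superlattice axial coords (rows of ab)
mfov_centers <- function(layout, ab) {
  S <- layout$mfov_spacing_nm
  cbind(S * (ab[, 1] + ab[, 2] / 2), S * ab[, 2] * sqrt(3) / 2)
}

#' Generate a 2D montage fixture: a phantom cut into hexagonal tiles
#'
#' Tiles are cut from one phantom image at their true (jittered) positions
#' while the manifest reports nominal lattice coordinates, emulating
#' beam/stage positioning error. Optional planted artifacts: multiplicative
#' per-beam linear gradients, per-beam integer brightness offsets, blank
#' (constant) tiles, and gross positional outliers.
#'
#' @param seed integer seed.
#' @param n_rings rings per mFOV (1 = 7 tiles).
#' @param mfov_ab integer matrix of mFOV axial superlattice coordinates.
#' @param tile_shape_px tile size c(h, w) px.
#' @param pixel_size_nm working pixel size.
#' @param jitter_sd_px Gaussian positional jitter (rounded to whole pixels).
#' @param gradient_range per-beam gradient amplitude range (e.g. c(0.8, 1.2));
#'   NULL disables.
#' @param offset_amp per-beam brightness offset amplitude (gray levels, zero-
#'   mean across beams); 0 disables.
#' @param blank_frac fraction of tiles replaced by constant gray.
#' @param phantom optional phantom matrix (generated when NULL).
#' @return list of class `montage_fixture`: `tiles` (list with `image`,
#'   `mfov_id`, `beam_id`, `nominal_xy` nm), `layout`, `phantom`,
#'   `truth` (`true_xy` nm, `gradients`, `offsets`, `blank`), `seed`,
#'   `pixel_size_nm`.
#' @export
montage_fixture <- function(seed = 1, n_rings = 1,
                            mfov_ab = rbind(c(0, 0), c(1, 0), c(0, 1)),
                            tile_shape_px = c(112, 128), pixel_size_nm = 16,
                            jitter_sd_px = 0.5,
                            gradient_range = NULL, offset_amp = 0,
                            blank_frac = 0, phantom = NULL) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  layout <- hex_layout(n_rings, tile_shape_px, pixel_size_nm)
  mc <- mfov_centers(layout, mfov_ab)
  B <- nrow(layout$beam_xy); M <- nrow(mfov_ab)
  nom <- NULL
  for (m in seq_len(M))
    nom <- rbind(nom, sweep(layout$beam_xy, 2, -mc[m, ]))
  n_tiles <- B * M
  th <- tile_shape_px[1]; tw <- tile_shape_px[2]
  jit_px <- matrix(round(stats::rnorm(2 * n_tiles, sd = jitter_sd_px)), n_tiles, 2)
  true_xy <- nom + jit_px * pixel_size_nm
  # phantom large enough to cover all tiles with margin
  ext_x <- range(true_xy[, 1]) / pixel_size_nm
  ext_y <- range(true_xy[, 2]) / pixel_size_nm
  margin <- 4L
  x0 <- floor(ext_x[1] - tw / 2) - margin; y0 <- floor(ext_y[1] - th / 2) - margin
  W <- ceiling(ext_x[2] + tw / 2) - x0 + 2 * margin
  H <- ceiling(ext_y[2] + th / 2) - y0 + 2 * margin
  if (is.null(phantom)) phantom <- fixture_phantom(H, W, seed = seed + 1)
  H <- nrow(phantom); W <- ncol(phantom)
  # per-beam artifacts
  gradients <- vector("list", B)
  for (b in seq_len(B)) {
    if (is.null(gradient_range)) gradients[[b]] <- matrix(1, th, tw)
    else {
      # beam gradients are mostly flat with a smooth rolloff toward the tile
      # border (scintillator/optics vignetting), as in real acquisitions:
      # plateau at a per-beam level, falling to the range minimum at the
      # farthest corner
      g <- coord_grid(th, tw)
      ctr <- c(stats::runif(1, 0.3, 0.7) * (tw - 1),
               stats::runif(1, 0.3, 0.7) * (th - 1))
      rr <- ((g$x - ctr[1])^2 + (g$y - ctr[2])^2)
      rr <- rr / max(rr)
      plateau <- stats::runif(1, 1, min(1.05, gradient_range[2]))
      roll <- pmax(0, (rr - 0.2) / 0.8)^1.5   # gentle, >= 1 um spatial scale
      gradients[[b]] <- matrix(plateau - (plateau - gradient_range[1]) * roll,
                               th, tw)
    }
  }
  offsets <- if (offset_amp > 0) {
    o <- round(stats::runif(B, -offset_amp, offset_amp)); round(o - mean(o))
  } else rep(0L, B)
  blank <- stats::runif(n_tiles) < blank_frac
  tiles <- vector("list", n_tiles)
  tl_px <- matrix(0L, n_tiles, 2)
  k <- 0L
  for (m in seq_len(M)) for (b in seq_len(B)) {
    k <- k + 1L
    cx <- true_xy[k, 1] / pixel_size_nm; cy <- true_xy[k, 2] / pixel_size_nm
    c0 <- round(cx - (tw - 1) / 2) - x0; r0 <- round(cy - (th - 1) / 2) - y0
    # truth records the actual integer cut position, not the ideal one
    true_xy[k, ] <- c((c0 + x0) + (tw - 1) / 2, (r0 + y0) + (th - 1) / 2) * pixel_size_nm
    tl_px[k, ] <- c(c0 + x0, r0 + y0)
    img <- phantom[r0 + seq_len(th), c0 + seq_len(tw), drop = FALSE]
    if (blank[k]) img <- matrix(128, th, tw)
    else img <- clamp255(round(img * gradients[[b]] + offsets[b]))
    tiles[[k]] <- list(image = img, mfov_id = m, beam_id = b,
                       nominal_xy = nom[k, ], pixel_size_nm = pixel_size_nm)
  }
  structure(list(tiles = tiles, layout = layout, phantom = phantom,
                 phantom_origin_nm = c(x0, y0) * pixel_size_nm,
                 truth = list(true_xy = true_xy, tl_px = tl_px,
                              gradients = gradients,
                              offsets = offsets, blank = blank),
                 seed = seed, pixel_size_nm = pixel_size_nm),
            class = "montage_fixture")
}

# smooth zero-mean-in-z random per-section displacement fields, evaluated on
# demand. Returns a function field(i, x_px, y_px) -> n x 2 displacements (px),
# plus the coarse control arrays.
smooth_field_stack <- function(n_sections, h, w, magnitude_px, spacing_px = 48,
                               seed = 1, zero_mean_z = TRUE) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  gh <- max(2L, ceiling(h / spacing_px) + 1L)
  gw <- max(2L, ceiling(w / spacing_px) + 1L)
  fx <- array(stats::rnorm(n_sections * gh * gw), c(gh, gw, n_sections))
  fy <- array(stats::rnorm(n_sections * gh * gw), c(gh, gw, n_sections))
  smooth2 <- function(a) box_filter(box_filter(a, 3), 3)
  for (i in seq_len(n_sections)) { fx[, , i] <- smooth2(fx[, , i]); fy[, , i] <- smooth2(fy[, , i]) }
  if (n_sections >= 3) {
    # deformations of neighboring sections are partially shared (e.g.
    # cutting-direction compression), keeping pairwise differences within
    # the same order as the per-section magnitude
    zsm <- function(a) {
      out <- a
      for (i in seq_len(n_sections)) {
        lo <- max(1, i - 1); hi <- min(n_sections, i + 1)
        out[, , i] <- (a[, , lo] + 2 * a[, , i] + a[, , hi]) / (2 + (lo != i) + (hi != i))
      }
      out
    }
    fx <- zsm(zsm(fx)); fy <- zsm(zsm(fy))
  }
  if (zero_mean_z && n_sections > 1) {
    fx <- sweep(fx, c(1, 2), apply(fx, c(1, 2), mean))
    fy <- sweep(fy, c(1, 2), apply(fy, c(1, 2), mean))
  }
  sc <- magnitude_px / stats::sd(c(fx, fy))
  fx <- fx * sc; fy <- fy * sc
  sx <- (w - 1) / (gw - 1); sy <- (h - 1) / (gh - 1)
  field <- function(i, x_px, y_px) {
    gx <- x_px / sx; gy <- y_px / sy
    cbind(bilinear_sample(fx[, , i], gx, gy, fill = 0),
          bilinear_sample(fy[, , i], gx, gy, fill = 0))
  }
  list(field = field, fx = fx, fy = fy, spacing_px = c(sx, sy))
}

#' Generate a serial-section stack fixture with planted deformations
#'
#' Sections share one phantom texture plus small per-section independent
#' noise (emulating section-to-section biological variation). Each section
#' is deformed by a planted transform, stored in the destination-to-source
#' convention: `section_i(a) = phantom(a + t_i(a))`, so the planted truth
#' `t_i` is directly comparable to the displacement the aligner must
#' recover.
#'
#' @param n_sections number of sections.
#' @param shape_px c(h, w) section size.
#' @param pixel_size_nm fixture pixel size (stacks are typically generated at
#'   a coarse pixel size).
#' @param kind `"none"`, `"rigid"` (smooth per-section rotation+translation
#'   series) or `"elastic"` (smooth random fields).
#' @param max_rot_deg,max_trans_px rigid series amplitudes.
#' @param magnitude_px elastic field RMS magnitude.
#' @param section_noise_sd per-section independent texture noise (gray levels).
#' @param roi_angle_noise_deg,roi_center_noise_px annotation error planted in
#'   the reported ROIs (ROIs report angle 0/center for `kind != "rigid"`).
#' @param seed integer seed.
#' @return list of class `stack_fixture`: `sections` (list of matrices),
#'   `rois` (per-section list: `center_nm`, `angle_deg`), `truth`
#'   (`t_field(i, x_px, y_px)` planted dest-to-source displacement in px,
#'   `kind`, rigid parameter series when applicable), `pixel_size_nm`,
#'   `shape_px`, `seed`.
#' @export
stack_fixture <- function(n_sections = 10, shape_px = c(192, 192),
                          pixel_size_nm = 512, kind = c("none", "rigid", "elastic"),
                          max_rot_deg = 10, max_trans_px = 30,
                          magnitude_px = 8, section_noise_sd = 10,
                          seed = 1) {
  kind <- match.arg(kind)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  h <- shape_px[1]; w <- shape_px[2]
  pad <- ceiling(0.35 * max(h, w)) + ceiling(max_trans_px)
  ph <- fixture_phantom(h + 2 * pad, w + 2 * pad, seed = seed + 100)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  smooth_series <- function(n, amp) {
    # low-frequency series: a handful of knots across the stack, so
    # section-to-section steps stay small relative to the amplitude
    v <- stats::rnorm(max(min(3, n), n %/% 10))
    s <- stats::spline(seq_along(v), v, n = n)$y
    if (n >= 5) s <- stats::filter(s, rep(0.2, 5), sides = 2, circular = TRUE)
    s <- s - mean(s)
    if (max(abs(s)) < 1e-12) rep(0, n) else s / max(abs(s)) * amp
  }
  angles <- trans_x <- trans_y <- rep(0, n_sections)
  efield <- NULL
  if (kind == "rigid") {
    angles <- smooth_series(n_sections, max_rot_deg)
    trans_x <- smooth_series(n_sections, max_trans_px)
    trans_y <- smooth_series(n_sections, max_trans_px)
  } else if (kind == "elastic") {
    # deformations are locally rigid: spatial wavelength on the order of
    # the section extent, as observed for real sectioning-induced warps
    efield <- smooth_field_stack(n_sections, h, w, magnitude_px,
                                 spacing_px = max(96, round(min(h, w) / 1.5)),
                                 seed = seed + 200)
  }
  t_field <- function(i, x_px, y_px) {
    if (kind == "rigid") {
      th <- angles[i] * pi / 180
      dx <- x_px - cx; dy <- y_px - cy
      cbind(cos(th) * dx - sin(th) * dy - dx + trans_x[i],
            sin(th) * dx + cos(th) * dy - dy + trans_y[i])
    } else if (kind == "elastic") {
      efield$field(i, x_px, y_px)
    } else {
      cbind(rep(0, length(x_px)), rep(0, length(x_px)))
    }
  }
  g <- coord_grid(h, w)
  sections <- vector("list", n_sections)
  for (i in seq_len(n_sections)) {
    t <- t_field(i, as.vector(g$x), as.vector(g$y))
    sx <- as.vector(g$x) + t[, 1] + pad
    sy <- as.vector(g$y) + t[, 2] + pad
    img <- matrix(bilinear_sample(ph, sx, sy, fill = 0), h, w)
    if (section_noise_sd > 0) {
      nz <- box_filter(matrix(stats::rnorm(h * w, sd = section_noise_sd * 2.5), h, w), 3)
      img <- img + nz
    }
    sections[[i]] <- clamp255(round(img))
  }
  rois <- lapply(seq_len(n_sections), function(i)
    list(center_nm = c(cx, cy) * pixel_size_nm, angle_deg = 0))
  structure(list(sections = sections, rois = rois,
                 truth = list(kind = kind, t_field = t_field,
                              angles_deg = angles,
                              trans_px = cbind(trans_x, trans_y)),
                 pixel_size_nm = pixel_size_nm, shape_px = shape_px,
                 seed = seed),
            class = "stack_fixture")
}

#' Generate a torn-section fixture with stitch annotations
#'
#' Cuts an image along a smooth y-monotone path, pulls the two halves apart
#' horizontally by `opening_px` (leaving a zero-filled gap), and generates
#' stitch control-point pairs straddling the tear at the given arclength
#' spacing.
#'
#' @param img clean section image.
#' @param opening_px total tear opening in px.
#' @param amp_px,period_px tear path sinusoid amplitude and period.
#' @param stitch_spacing_px spacing of annotated pairs along the tear.
#' @param seed integer seed (path phase).
#' @return list: `torn` (matrix), `pairs` (list of `a`, `b` N x 2 point
#'   matrices, 0-based px), `midline_x(y)` true path function, `clean`.
#' @export
tear_fixture <- function(img, opening_px = 8, amp_px = 6, period_px = 120,
                         stitch_spacing_px = 14, seed = 1) {
  h <- nrow(img); w <- ncol(img)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  phase <- stats::runif(1, 0, 2 * pi)
  cx <- (w - 1) / 2
  f <- function(y) cx + amp_px * sin(2 * pi * y / period_px + phase)
  g <- coord_grid(h, w)
  mid <- matrix(f(as.vector(g$y)), h, w)
  half <- opening_px / 2
  torn <- matrix(0, h, w)
  left <- g$x + half < mid
  right <- g$x - half >= mid
  lv <- bilinear_sample(img, as.vector(g$x[left]) + half, as.vector(g$y[left]))
  rv <- bilinear_sample(img, as.vector(g$x[right]) - half, as.vector(g$y[right]))
  torn[left] <- ifelse(is.na(lv), 0, lv)
  torn[right] <- ifelse(is.na(rv), 0, rv)
  ys <- seq(2, h - 3, by = stitch_spacing_px)
  pairs <- list(a = cbind(f(ys) - half, ys), b = cbind(f(ys) + half, ys))
  list(torn = torn, pairs = pairs, midline_x = f, clean = img,
       opening_px = opening_px)
}

#' Measure probe-point misregistration against planted ground truth
#'
#' Compares the recovered destination-to-source displacement of an alignment
#' (`chain`, see [invert_chain()]) with the planted fixture truth at random
#' probe points. The global gauge freedom of difference-system solutions (a
#' common offset per probe across sections) is removed before measuring.
#'
#' @param chain a `transform_chain` for the fixture stack.
#' @param fixture a [stack_fixture()].
#' @param n_probes number of random probe points.
#' @param seed probe sampling seed.
#' @param margin_px border margin excluded from probing.
#' @return list: `per_probe` (n_probes x n_sections error magnitudes, px),
#'   `rms_px`, `max_px`.
#' @export
probe_registration <- function(chain, fixture, n_probes = 10, seed = 1,
                               margin_px = NULL, gauge = c("offset", "linear"),
                               metric = c("truth", "pairwise")) {
  gauge <- match.arg(gauge)
  metric <- match.arg(metric)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  h <- fixture$shape_px[1]; w <- fixture$shape_px[2]
  if (is.null(margin_px)) margin_px <- round(0.2 * min(h, w))
  px <- stats::runif(n_probes, margin_px, w - 1 - margin_px)
  py <- stats::runif(n_probes, margin_px, h - 1 - margin_px)
  n_sec <- length(fixture$sections)
  ps <- fixture$pixel_size_nm
  if (metric == "pairwise") {
    # phantom position shown at each probe by every aligned section; mutual
    # registration error = difference between consecutive sections (gauge
    # free by construction)
    phi <- array(NA_real_, c(n_probes, n_sec, 2))
    for (i in seq_len(n_sec)) {
      a <- invert_chain(chain, i, px * ps, py * ps) / ps
      phi[, i, ] <- a + fixture$truth$t_field(i, a[, 1], a[, 2])
    }
    d <- phi[, -1, , drop = FALSE] - phi[, -n_sec, , drop = FALSE]
    mag <- sqrt(d[, , 1]^2 + d[, , 2]^2)
    return(list(per_probe = mag, rms_px = sqrt(mean(mag^2)), max_px = max(mag)))
  }
  err <- array(NA_real_, c(n_probes, n_sec, 2))
  for (i in seq_len(n_sec)) {
    src <- invert_chain(chain, i, px * ps, py * ps) / ps   # recovered, px
    # true dest-to-source lookup: the point a with a + t_i(a) = q
    a <- cbind(px, py)
    for (it in 1:25) a <- cbind(px, py) - fixture$truth$t_field(i, a[, 1], a[, 2])
    err[, i, ] <- src - a
  }
  # remove the solver's gauge freedom per probe across sections: a global
  # offset (all solves) and, for trend-removed stages, a linear z-trend
  if (gauge == "offset") {
    err <- sweep(err, c(1, 3), apply(err, c(1, 3), mean))
  } else {
    z <- seq_len(n_sec)
    for (p in seq_len(n_probes)) for (k in 1:2)
      err[p, , k] <- remove_linear_trend(err[p, , k], z)$values
  }
  mag <- sqrt(err[, , 1]^2 + err[, , 2]^2)
  list(per_probe = mag, rms_px = sqrt(mean(mag^2)), max_px = max(mag))
}

#' Compare a rendered montage against the fixture phantom
#'
#' Anchors the montage canvas to the phantom using the first tile's exact
#' cut position (an integer pixel offset, so the comparison involves no
#' resampling blur) and reports correlation and mean absolute difference
#' over the covered region.
#'
#' @param fixture a [montage_fixture()].
#' @param result output of [montage_section()] (needs `image`, `weight`,
#'   `origin_nm`, `coords_nm`).
#' @return list: `correlation`, `mad` (gray levels), `n_pixels`.
#' @export
compare_montage_phantom <- function(fixture, result) {
  ps <- fixture$pixel_size_nm
  th <- fixture$layout$tile_shape_px[1]; tw <- fixture$layout$tile_shape_px[2]
  origin_px <- result$origin_nm / ps
  canvas_tl1 <- round(result$coords_nm[1, ] / ps - (c(tw, th) - 1) / 2) - origin_px
  shift <- fixture$truth$tl_px[1, ] - fixture$phantom_origin_nm / ps -
    round(canvas_tl1)
  g <- coord_grid(nrow(result$image), ncol(result$image))
  pv <- bilinear_sample(fixture$phantom, as.vector(g$x) + shift[1],
                        as.vector(g$y) + shift[2], fill = NA_real_)
  m <- as.vector(result$weight) > 0 & !is.na(pv)
  list(correlation = stats::cor(as.vector(result$image)[m], pv[m]),
       mad = mean(abs(as.vector(result$image)[m] - pv[m])),
       n_pixels = sum(m))
}
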