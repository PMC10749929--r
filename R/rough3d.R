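# 3D coarse and rough alignment: ROI-based re-orientation into the rough
# bounding box, feature-based pairwise constrained-affine estimation across
# i +/- n neighbors, conversion of affines to grid vector fields, blockwise
# per-grid-point delta least squares with trend removal, and refit to one
# no-shear affine per section.
#
# Sign conventions: solved per-section warp fields are stored as
# destination-to-source displacements in the rough-bbox frame (sampling a
# section at q + u(q) shows the content that belongs at q), matching the
# remap order used at export.

#' Coarse-align a section into the rough bounding box
#'
#' Rotates the section by the ROI angle about the ROI center and translates
#' the ROI center to the bounding-box center, cropping to the box. Returns
#' both the resampled image and the destination-to-source affine (bbox
#' coordinates to section coordinates, nm).
#'
#' @param section section image matrix.
#' @param roi list with `center_nm` (x, y) and `angle_deg`.
#' @param bbox_px c(h, w) of the rough bounding box in pixels.
#' @param pixel_size_nm pixel size.
#' @return list: `image` (bbox_px), `affine` (`affine2d`, bbox nm -> section
#'   nm).
#' @export
coarse_align <- function(section, roi, bbox_px = dim(section),
                         pixel_size_nm = 16) {
  ctr <- roi$center_nm
  if (ctr[1] < 0 || ctr[2] < 0 ||
      ctr[1] > (ncol(section) - 1) * pixel_size_nm ||
      ctr[2] > (nrow(section) - 1) * pixel_size_nm)
    stop("ROI center outside the section image")
  th <- roi$angle_deg * pi / 180
  cb <- c((bbox_px[2] - 1) / 2, (bbox_px[1] - 1) / 2) * pixel_size_nm
  L <- rot2(th)
  A <- affine2d(L, ctr - as.vector(L %*% cb))
  g <- coord_grid(bbox_px[1], bbox_px[2])
  src <- apply_affine(A, cbind(as.vector(g$x), as.vector(g$y)) * pixel_size_nm) /
    pixel_size_nm
  rm <- remap_image(section, matrix(src[, 1], bbox_px[1], bbox_px[2]),
                    matrix(src[, 2], bbox_px[1], bbox_px[2]), fill = 0)
  list(image = rm$image, affine = A)
}

#' Detect blob features with orientation-normalized patch descriptors
#'
#' Default feature provider for the rough alignment: multi-scale
#' difference-of-Gaussians extrema (scale-space blobs) with descriptors
#' built from an oriented intensity patch. Patch orientation is normalized
#' by the intensity-centroid angle, giving robustness to the modest
#' section-to-section rotations left after coarse alignment. Any provider
#' returning `(keypoints, descriptors)` can be substituted.
#'
#' @param img image matrix (typically a coarse-aligned section at a coarse
#'   pixel size).
#' @param pixel_size_nm pixel size (keypoints are reported in nm).
#' @param n_max maximum number of keypoints (strongest responses kept).
#' @param threshold minimum absolute DoG response (gray levels).
#' @return list: `keypoints` (n x 2 nm), `descriptors` (n x d matrix,
#'   row-normalized), `response`.
#' @export
detect_features <- function(img, pixel_size_nm = 16, n_max = 600, threshold = 1.5) {
  sig <- c(1.6, 2.26, 3.2, 4.53, 6.4)
  blur <- lapply(sig, function(s)
    t(as.matrix(EBImage::gblur(EBImage::Image(t(img)), sigma = s))))
  kps <- NULL
  h <- nrow(img); w <- ncol(img)
  for (k in seq_len(length(sig) - 1)) {
    d <- blur[[k]] - blur[[k + 1]]
    a <- abs(d)
    mx <- matrix(-Inf, h, w)
    mx[2:(h - 1), 2:(w - 1)] <- pmax(
      a[1:(h - 2), 1:(w - 2)], a[1:(h - 2), 2:(w - 1)], a[1:(h - 2), 3:w],
      a[2:(h - 1), 1:(w - 2)],                          a[2:(h - 1), 3:w],
      a[3:h,       1:(w - 2)], a[3:h,       2:(w - 1)], a[3:h,       3:w])
    loc <- which(a > mx & a > threshold, arr.ind = TRUE)
    if (nrow(loc)) {
      margin <- ceiling(10 * sig[k] / 1.6) + 2
      keep <- loc[, 1] > margin & loc[, 1] < h - margin &
        loc[, 2] > margin & loc[, 2] < w - margin
      loc <- loc[keep, , drop = FALSE]
      if (nrow(loc))
        kps <- rbind(kps, cbind(loc[, 2] - 1, loc[, 1] - 1, sig[k],
                                a[loc]))
    }
  }
  if (is.null(kps) || nrow(kps) == 0)
    return(list(keypoints = matrix(0, 0, 2), descriptors = matrix(0, 0, 0),
                response = numeric(0)))
  kps <- kps[order(-kps[, 4]), , drop = FALSE]
  kps <- utils::head(kps, n_max)
  # oriented patch descriptor: 8x8 samples at 1.5*sigma spacing
  n <- nrow(kps); grid <- seq(-3.5, 3.5, by = 1)
  gx <- as.vector(outer(rep(1, 8), grid)); gy <- as.vector(outer(grid, rep(1, 8)))
  desc <- matrix(0, n, 64)
  for (i in seq_len(n)) {
    x0 <- kps[i, 1]; y0 <- kps[i, 2]; s <- kps[i, 3]
    b <- blur[[which.min(abs(sig - s))]]
    sp <- 1.5 * s
    # intensity-centroid orientation over the unrotated patch
    px <- x0 + gx * sp; py <- y0 + gy * sp
    v <- bilinear_sample(b, px, py, fill = NA)
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    vc <- v - mean(v)
    ang <- atan2(sum(gy * vc), sum(gx * vc))
    ca <- cos(ang); sa <- sin(ang)
    rx <- ca * gx - sa * gy; ry <- sa * gx + ca * gy
    v <- bilinear_sample(b, x0 + rx * sp, y0 + ry * sp, fill = NA)
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    v <- v - mean(v)
    nv <- sqrt(sum(v^2))
    desc[i, ] <- if (nv > 1e-9) v / nv else v
  }
  list(keypoints = kps[, 1:2, drop = FALSE] * pixel_size_nm,
       descriptors = desc, response = kps[, 4])
}

#' Match two feature sets with the Lowe ratio test
#'
#' For every source descriptor, finds the nearest and second-nearest
#' destination descriptors; the match is kept iff
#' `d(second) / d(nearest) >= lowe_ratio`. Matches are not necessarily
#' one-to-one.
#'
#' @param featA,featB outputs of [detect_features()].
#' @param lowe_ratio ratio threshold (default 1.42).
#' @return list: `src`, `dst` (n x 2 nm keypoint matrices), `dist`.
#' @export
match_sections <- function(featA, featB, lowe_ratio = 1.42) {
  nA <- nrow(featA$descriptors); nB <- nrow(featB$descriptors)
  if (nA == 0 || nB < 2)
    return(list(src = matrix(0, 0, 2), dst = matrix(0, 0, 2), dist = numeric(0)))
  d2 <- outer(rowSums(featA$descriptors^2), rep(1, nB)) +
    outer(rep(1, nA), rowSums(featB$descriptors^2)) -
    2 * featA$descriptors %*% t(featB$descriptors)
  d2[d2 < 0] <- 0
  nn1 <- max.col(-d2, ties.method = "first")
  d1 <- d2[cbind(seq_len(nA), nn1)]
  d2m <- d2; d2m[cbind(seq_len(nA), nn1)] <- Inf
  dsec <- d2m[cbind(seq_len(nA), max.col(-d2m, ties.method = "first"))]
  keep <- sqrt(dsec) >= lowe_ratio * sqrt(d1)
  list(src = featA$keypoints[keep, , drop = FALSE],
       dst = featB$keypoints[nn1[keep], , drop = FALSE],
       dist = sqrt(d1[keep]))
}

#' Pairwise constrained affines between neighboring sections
#'
#' For each section pair (i, i+n), n = 1..n_max, matches features and fits a
#' RANSAC-constrained affine. Pairs failing the minimum match count or the
#' maximum-translation heuristic are flagged bad.
#'
#' @param features per-section feature list.
#' @param n_max neighbor span.
#' @param config [pipeline_config()]; `min_keypoint_radius_nm` > 0 enables
#'   the minimal radial-distribution heuristic on the inlier keypoints
#'   (off by default).
#' @param constraint affine constraint (production: "rigid").
#' @param seed RANSAC seed.
#' @return data.frame-like list of pairs: `i`, `j`, `transform`, `ok`,
#'   `n_inliers`, `inlier_src` (keypoints, for the distance cutoff).
#' @export
neighbor_affines <- function(features, n_max = 4, config = pipeline_config(),
                             constraint = "rigid", seed = 1) {
  n_sec <- length(features)
  pairs <- list()
  for (i in seq_len(n_sec)) for (n in seq_len(n_max)) {
    j <- i + n
    if (j > n_sec) next
    m <- match_sections(features[[i]], features[[j]], config$lowe_ratio)
    r <- ransac_fit(m$src, m$dst, constraint,
                    tolerance_nm = config$rough_ransac_tol_nm,
                    min_inliers = config$min_matches,
                    max_translation_nm = config$max_translation_nm,
                    iters = config$ransac_iters,
                    seed = seed + 977L * i + n)
    # optional heuristic (off by default): reject pairs whose inlier
    # keypoints cluster too tightly to constrain a global affine
    if (r$ok && config$min_keypoint_radius_nm > 0) {
      ks <- m$src[r$inliers, , drop = FALSE]
      rad <- sqrt(mean(rowSums(sweep(ks, 2, colMeans(ks))^2)))
      if (rad < config$min_keypoint_radius_nm)
        r <- list(ok = FALSE, transform = NULL, inliers = r$inliers,
                  n_inliers = r$n_inliers,
                  reason = "keypoint radial distribution below minimum")
    }
    pairs[[length(pairs) + 1]] <- list(
      i = i, j = j, ok = r$ok, transform = r$transform,
      n_inliers = r$n_inliers, n_matches = nrow(m$src),
      inlier_src = if (r$ok) m$src[r$inliers, , drop = FALSE] else NULL,
      reason = r$reason)
  }
  pairs
}

#' Hexagonal grid of points covering a rectangle
#'
#' @param width_nm,height_nm extent.
#' @param spacing_nm lattice spacing (center distance).
#' @return n x 2 matrix of points (nm), row-major by hex row.
#' @export
hex_grid_points <- function(width_nm, height_nm, spacing_nm) {
  dy <- spacing_nm * sqrt(3) / 2
  # rows and columns extend to cover the full extent (the last row/point may
  # lie just beyond it), so interpolation inside the rectangle never clamps
  rows <- seq(0, by = dy, length.out = ceiling(height_nm / dy) + 1L)
  pts <- NULL
  for (r in seq_along(rows)) {
    off <- if (r %% 2 == 0) spacing_nm / 2 else 0
    xs <- seq(off - (if (off > 0) spacing_nm else 0), by = spacing_nm,
              length.out = ceiling((width_nm + spacing_nm) / spacing_nm) + 1L)
    xs <- xs[xs > -spacing_nm - 1e-9]
    pts <- rbind(pts, cbind(xs, rows[r]))
  }
  unname(pts)
}

# replace each hex grid point by the centroid of itself and its lattice
# neighbors (the Voronoi-cell centroid; interior points are unchanged)
voronoi_centroids <- function(grid, spacing_nm) {
  n <- nrow(grid)
  out <- grid
  for (i in seq_len(n)) {
    d <- sqrt((grid[, 1] - grid[i, 1])^2 + (grid[, 2] - grid[i, 2])^2)
    nb <- d < 1.1 * spacing_nm            # includes self
    out[i, ] <- colMeans(grid[nb, , drop = FALSE])
  }
  out
}

#' Evaluate pairwise affines on a grid, producing vector fields
#'
#' The delta at each grid point is `T(p) - p`; grid points farther than the
#' keypoint cutoff from any inlier source keypoint are invalidated. The grid
#' is replaced by its Voronoi-cell centroid positions before solving.
#'
#' @param pairs output of [neighbor_affines()].
#' @param bbox_nm c(width, height) of the rough bounding box.
#' @param config [pipeline_config()].
#' @return list: `grid` (centroid positions, nm), `comparisons` (list of
#'   `i`, `j`, `delta` (n x 2), `valid`).
#' @export
affines_to_fields <- function(pairs, bbox_nm, config = pipeline_config()) {
  grid0 <- hex_grid_points(bbox_nm[1], bbox_nm[2], config$rough_grid_nm)
  grid <- voronoi_centroids(grid0, config$rough_grid_nm)
  comps <- list()
  for (p in pairs) {
    if (!p$ok) next
    d <- apply_affine(p$transform, grid) - grid
    valid <- rep(TRUE, nrow(grid))
    if (!is.null(p$inlier_src) && nrow(p$inlier_src)) {
      kd2 <- outer(rowSums(grid^2), rep(1, nrow(p$inlier_src))) +
        outer(rep(1, nrow(grid)), rowSums(p$inlier_src^2)) -
        2 * grid %*% t(p$inlier_src)
      valid <- sqrt(pmax(apply(kd2, 1, min), 0)) <= config$keypoint_cutoff_nm
    }
    comps[[length(comps) + 1]] <- list(i = p$i, j = p$j, delta = d, valid = valid)
  }
  list(grid = grid, comparisons = comps)
}

# solve the z-chain difference system for every grid point independently,
# blockwise in z, removing the per-grid-point linear trend of each block
solve_grid_deltas <- function(fields, n_sections, config,
                              weights_fn = function(n_off) 1,
                              l2 = 0, detrend = TRUE,
                              block_context = config$block_context,
                              block_solve = config$block_solve) {
  grid <- fields$grid
  ng <- nrow(grid)
  u <- array(0, c(n_sections, ng, 2))     # dest-to-source displacements
  counts <- matrix(0L, n_sections, ng)
  starts <- seq(1, n_sections, by = block_solve)
  pad <- max(0, (block_context - block_solve) %/% 2)
  for (s0 in starts) {
    s1 <- min(s0 + block_solve - 1, n_sections)
    c0 <- max(1, s0 - pad); c1 <- min(n_sections, s1 + pad)
    nn <- c1 - c0 + 1
    for (gpt in seq_len(ng)) {
      src <- integer(0); dst <- integer(0); del <- NULL; w <- numeric(0)
      for (cmp in fields$comparisons) {
        if (!cmp$valid[gpt]) next
        if (cmp$i < c0 || cmp$j > c1) next
        src <- c(src, cmp$i - c0 + 1); dst <- c(dst, cmp$j - c0 + 1)
        del <- rbind(del, cmp$delta[gpt, ])
        wr <- weights_fn(abs(cmp$j - cmp$i))
        if (!is.null(cmp$weight)) wr <- wr * cmp$weight[gpt]
        w <- c(w, wr)
      }
      if (length(src) == 0) { counts[s0:s1, gpt] <- NA; next }
      g <- tryCatch(delta_graph(nn, src, dst, del, weight = w),
                    error = function(e) NULL)
      sol <- tryCatch(solve_deltas(g, l2 = l2), error = function(e) NULL)
      if (is.null(sol)) { counts[s0:s1, gpt] <- NA; next }
      # edge deltas are t_i - t_j for dest-to-source displacements t, so the
      # solved coordinates are x_i = -t_i + gauge; the dest-to-source warp
      # that aligns section i is u_i = x_i (sampling at q + u shows the
      # content belonging at q)
      x <- sol$coords
      if (detrend && nn >= 2) x <- remove_linear_trend(x, seq_len(nn))$values
      u[s0:s1, gpt, ] <- x[(s0 - c0 + 1):(s1 - c0 + 1), , drop = FALSE]
      counts[s0:s1, gpt] <- length(src)
    }
  }
  dropped <- colSums(is.na(counts)) == n_sections
  active <- fields$active %||% rep(TRUE, ng)
  if (any(dropped & active))
    warning(sum(dropped & active),
            " active grid point(s) had no valid deltas and were dropped")
  list(u = u, grid = grid, n_deltas = counts, dropped = dropped)
}

#' Rough-alignment delta solve
#'
#' Per grid point independently, reconciles all (i, i+/-n) deltas over the
#' z-stack into one displacement per section, applied blockwise in z with
#' overlapping context; the per-grid-point linear trend (including offset)
#' of each block solution is removed. Returned displacements are
#' destination-to-source.
#'
#' @param fields output of [affines_to_fields()].
#' @param n_sections stack size.
#' @param config [pipeline_config()].
#' @return list: `u` (n_sections x n_grid x 2 nm), `grid`, `n_deltas`,
#'   `dropped`.
#' @export
rough_delta_solve <- function(fields, n_sections, config = pipeline_config()) {
  solve_grid_deltas(fields, n_sections, config, detrend = TRUE)
}

#' Refit a section's resolved vector field with a no-shear affine
#'
#' Fits the constrained (zero-shear) affine mapping `p -> p + u(p)` over the
#' valid grid points; this is the section's rough transform
#' (destination-to-source, rough-bbox frame).
#'
#' @param grid n x 2 grid positions (nm).
#' @param u n x 2 displacements (nm).
#' @param valid logical mask of usable grid points.
#' @param constraint affine constraint (default "noshear").
#' @return `affine2d` (identity, with a warning, when < 2 valid points).
#' @export
refit_section_affine <- function(grid, u, valid = NULL, constraint = "noshear") {
  if (is.null(valid)) valid <- rep(TRUE, nrow(grid))
  if (sum(valid) < 2) {
    warning("fewer than 2 valid grid points; returning identity")
    return(affine2d())
  }
  fit_affine(grid[valid, , drop = FALSE],
             grid[valid, , drop = FALSE] + u[valid, , drop = FALSE],
             constraint)
}

#' Run coarse + rough alignment on a section stack
#'
#' @param sections list of section image matrices.
#' @param rois per-section ROI list (`center_nm`, `angle_deg`).
#' @param pixel_size_nm stack pixel size.
#' @param config [pipeline_config()].
#' @param detector feature detector function (default [detect_features()]).
#' @param constraint pairwise affine constraint (production "rigid").
#' @param seed RANSAC seed.
#' @return list of class `rough_alignment`: `coarse` (per-section affine),
#'   `rough` (per-section no-shear `affine2d`), `coarse_images`, `fields`,
#'   `resolved` (solve output), `pairs`, `bbox_px`.
#' @export
rough_align_stack <- function(sections, rois, pixel_size_nm = 16,
                              config = pipeline_config(),
                              detector = detect_features,
                              constraint = "rigid", seed = 1) {
  n <- length(sections)
  bbox_px <- dim(sections[[1]])
  co <- lapply(seq_len(n), function(i)
    coarse_align(sections[[i]], rois[[i]], bbox_px, pixel_size_nm))
  imgs <- lapply(co, `[[`, "image")
  feats <- lapply(imgs, detector, pixel_size_nm = pixel_size_nm)
  pairs <- neighbor_affines(feats, config$rough_n_neighbors, config,
                            constraint = constraint, seed = seed)
  bbox_nm <- c((bbox_px[2] - 1), (bbox_px[1] - 1)) * pixel_size_nm
  fields <- affines_to_fields(pairs, bbox_nm, config)
  resolved <- rough_delta_solve(fields, n, config)
  rough <- lapply(seq_len(n), function(i)
    refit_section_affine(fields$grid, resolved$u[i, , ],
                         valid = !resolved$dropped))
  structure(list(coarse = lapply(co, `[[`, "affine"), rough = rough,
                 coarse_images = imgs, fields = fields, resolved = resolved,
                 pairs = pairs, bbox_px = bbox_px,
                 pixel_size_nm = pixel_size_nm),
            class = "rough_alignment")
}
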