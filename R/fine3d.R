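# Elastic fine and ultrafine alignment: masked hexagonal grids,
# rotation-swept nxcorr deltas to i +/- n neighbors, RANSAC-quadratic plus
# neighborhood outlier rejection, MLS replacement, affine filtering, and the
# weighted / ridge per-grid-point delta solve. Solved per-section warp
# fields are destination-to-source displacements in the aligned frame.

#' Parameter bundle for a fine or ultrafine pass
#'
#' Pulls the stage parameters out of the pipeline configuration. Production
#' values: fine grid 16 um, crops 32 / 4.8 um, +/-4 neighbors, affine filter
#' 61 um, no ridge; ultrafine grid 2 um, crops 12.8 / 3.2 um, +/-2
#' neighbors, no affine filter, L2 = 0.05. Both sweep template rotations
#' over +/-15 degrees in 3 degree steps.
#'
#' @param config [pipeline_config()].
#' @param stage `"fine"` or `"ultrafine"`.
#' @return named list of stage parameters.
#' @export
fine_params <- function(config = pipeline_config(), stage = c("fine", "ultrafine")) {
  stage <- match.arg(stage)
  if (stage == "fine") {
    p <- list(grid_nm = config$fine_grid_nm, src_crop_nm = config$fine_src_crop_nm,
              dst_crop_nm = config$fine_dst_crop_nm,
              n_neighbors = config$fine_n_neighbors,
              affine_filter = TRUE, l2 = config$fine_l2)
  } else {
    p <- list(grid_nm = config$ultra_grid_nm, src_crop_nm = config$ultra_src_crop_nm,
              dst_crop_nm = config$ultra_dst_crop_nm,
              n_neighbors = config$ultra_n_neighbors,
              affine_filter = FALSE, l2 = config$ultra_l2)
  }
  stopifnot(p$dst_crop_nm < p$src_crop_nm)
  c(p, list(angles = config$rot_sweep_deg,
            ransac_tol_nm = config$fine_ransac_tol_nm,
            reconsider_diam_nm = config$reconsider_diam_nm,
            replaced_weight = config$replaced_weight,
            affine_box_nm = config$affine_filter_box_nm,
            neighbor_weights = config$neighbor_weights,
            stage = stage))
}

#' Hexagonal alignment grid restricted to ROI and tissue mask
#'
#' Grid points are active iff they fall inside the acquisition ROI scaled by
#' the configured factor (110%) and inside a dilated version of the tissue
#' mask; with neither provided, all points are active.
#'
#' @param bbox_px c(h, w) of the aligned frame.
#' @param pixel_size_nm pixel size.
#' @param spacing_nm grid spacing.
#' @param roi optional list: `center_nm`, `angle_deg`, `halfsize_nm` (c(hx,
#'   hy) rectangle half-extent).
#' @param mask optional `tissue_mask`.
#' @param config [pipeline_config()].
#' @return list: `grid` (n x 2 nm), `active` (logical).
#' @export
make_masked_grid <- function(bbox_px, pixel_size_nm = 16, spacing_nm,
                             roi = NULL, mask = NULL,
                             config = pipeline_config()) {
  stopifnot(spacing_nm > 0)
  bw <- (bbox_px[2] - 1) * pixel_size_nm
  bh <- (bbox_px[1] - 1) * pixel_size_nm
  grid <- hex_grid_points(bw, bh, spacing_nm)
  active <- rep(TRUE, nrow(grid))
  if (!is.null(roi) && !is.null(roi$halfsize_nm)) {
    th <- -(roi$angle_deg %||% 0) * pi / 180
    d <- sweep(grid, 2, roi$center_nm)
    lx <- cos(th) * d[, 1] - sin(th) * d[, 2]
    ly <- sin(th) * d[, 1] + cos(th) * d[, 2]
    active <- active & abs(lx) <= roi$halfsize_nm[1] * config$roi_scale &
      abs(ly) <= roi$halfsize_nm[2] * config$roi_scale
  }
  if (!is.null(mask)) {
    m <- mask$mask
    md <- t(as.matrix(EBImage::dilate(EBImage::Image(t(m) * 1),
                                      EBImage::makeBrush(3, "box")))) > 0.5
    mx <- grid[, 1] / mask$pixel_size_nm
    my <- grid[, 2] / mask$pixel_size_nm
    iy <- pmin(pmax(round(my) + 1, 1), nrow(md))
    ix <- pmin(pmax(round(mx) + 1, 1), ncol(md))
    active <- active & md[cbind(iy, ix)]
  }
  list(grid = grid, active = active)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Measure grid vector fields between neighboring sections
#'
#' For every active grid point and every neighbor pair (i, i+n), matches the
#' destination section's small template crop inside the source section's
#' larger crop (both preprocessed, template rotation-swept) and records the
#' resulting delta. The stored delta follows the z-chain convention used by
#' the delta solver (`delta = t_i - t_j` for destination-to-source
#' displacements `t`).
#'
#' @param sections list of aligned section images (same frame).
#' @param grid output of [make_masked_grid()].
#' @param params [fine_params()].
#' @param pixel_size_nm stack pixel size.
#' @param config [pipeline_config()].
#' @return list (vector-field set): `grid`, `active`, `comparisons` (list of
#'   `i`, `j`, `delta` (n x 2 nm), `valid`, `peak`, `angle`).
#' @export
measure_fine_deltas <- function(sections, grid, params, pixel_size_nm = 16,
                                config = pipeline_config()) {
  n_sec <- length(sections)
  pp <- lapply(sections, function(s) preprocess_image(s, pixel_size_nm, config))
  src_r <- max(4L, round(params$src_crop_nm / pixel_size_nm / 2))
  dst_r <- max(2L, round(params$dst_crop_nm / pixel_size_nm / 2))
  gpx <- round(grid$grid / pixel_size_nm)
  ng <- nrow(gpx)
  h <- nrow(sections[[1]]); w <- ncol(sections[[1]])
  crop <- function(img, cx, cy, r)
    img[(cy - r + 1):(cy + r) + 1, (cx - r + 1):(cx + r) + 1, drop = FALSE]
  comps <- list()
  for (i in seq_len(n_sec)) for (nn in seq_len(params$n_neighbors)) {
    j <- i + nn
    if (j > n_sec) next
    delta <- matrix(NA_real_, ng, 2)
    valid <- rep(FALSE, ng)
    peak <- rep(NA_real_, ng); angle <- rep(NA_real_, ng)
    for (g in seq_len(ng)) {
      if (!grid$active[g]) next
      cx <- gpx[g, 1]; cy <- gpx[g, 2]
      if (cx - src_r < 0 || cy - src_r < 0 || cx + src_r > w - 1 || cy + src_r > h - 1)
        next
      if (!pp[[i]]$valid || !pp[[j]]$valid) next
      main <- crop(pp[[i]]$image, cx, cy, src_r)
      tmpl <- crop(pp[[j]]$image, cx, cy, dst_r)
      if (stats::var(as.vector(tmpl)) < 1e-20) next
      r <- nxcorr_match_rotated(main, tmpl, params$angles, pixel_size_nm)
      if (!r$valid) next
      delta[g, ] <- -r$delta_nm              # o = t_j - t_i; store t_i - t_j
      valid[g] <- TRUE
      peak[g] <- r$peak_value; angle[g] <- r$best_angle_deg
    }
    comps[[length(comps) + 1]] <- list(i = i, j = j, delta = delta,
                                       valid = valid, peak = peak, angle = angle)
  }
  list(grid = grid$grid, active = grid$active, comparisons = comps)
}

quad_basis <- function(p, scale_nm) {
  x <- p[, 1] / scale_nm; y <- p[, 2] / scale_nm
  cbind(1, x, y, x^2, x * y, y^2)
}

#' Outlier detection on one vector-field comparison
#'
#' RANSAC against a quadratic-affine model (per-axis polynomial in 1, x, y,
#' x^2, xy, y^2) with the configured tolerance classifies deltas; rejected
#' deltas are re-admitted when their direction and magnitude agree with the
#' most similar inlier vectors inside the reconsideration neighborhood.
#'
#' @param delta n x 2 measured deltas (nm; NA where unmeasured).
#' @param grid n x 2 grid positions (nm).
#' @param measured logical: which grid points carry a measurement.
#' @param active logical: grid points inside ROI/mask (denominator of the
#'   inlier fraction).
#' @param config [pipeline_config()].
#' @param seed RANSAC seed.
#' @return list: `inlier` (logical per grid point), `inlier_fraction`,
#'   `readmitted`.
#' @export
detect_outliers <- function(delta, grid, measured, active,
                            config = pipeline_config(), seed = 1) {
  idx <- which(measured)
  n <- length(idx)
  inlier <- rep(FALSE, nrow(grid))
  if (n < 3) return(list(inlier = inlier, inlier_fraction = 0,
                         readmitted = rep(FALSE, nrow(grid))))
  scale_nm <- max(stats::sd(grid[, 1]), stats::sd(grid[, 2]), 1)
  X <- quad_basis(grid[idx, , drop = FALSE], scale_nm)
  Y <- delta[idx, , drop = FALSE]
  k <- 6L
  use_quad <- n >= 2 * k
  if (!use_quad) {
    warning("too few points for the quadratic model; falling back to linear affine")
    X <- X[, 1:3, drop = FALSE]; k <- 3L
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  tol <- config$fine_ransac_tol_nm
  best <- NULL; best_n <- -1L
  for (it in seq_len(config$ransac_iters)) {
    s <- sample.int(n, k)
    cf <- tryCatch(qr.coef(qr(X[s, , drop = FALSE]), Y[s, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(cf) || any(is.na(cf))) next
    r <- sqrt(rowSums((X %*% cf - Y)^2))
    m <- r <= tol
    if (sum(m) > best_n) { best_n <- sum(m); best <- m }
  }
  if (is.null(best)) return(list(inlier = inlier, inlier_fraction = 0,
                                 readmitted = rep(FALSE, nrow(grid))))
  m <- best
  for (rep in 1:5) {
    cf <- qr.coef(qr(X[m, , drop = FALSE]), Y[m, , drop = FALSE])
    if (any(is.na(cf))) break
    m2 <- sqrt(rowSums((X %*% cf - Y)^2)) <= tol
    if (all(m2 == m)) break
    m <- m2
  }
  inlier[idx[m]] <- TRUE
  # neighborhood re-admission of rejected deltas: a delta agreeing in angle
  # and magnitude with the most similar measured vectors around it (e.g. a
  # coherent locally warped patch) is kept despite the global model
  readmit <- rep(FALSE, nrow(grid))
  rad <- config$reconsider_diam_nm / 2
  out_idx <- idx[!m]
  if (length(idx) > config$readmit_k && length(out_idx)) {
    for (o in out_idx) {
      cand <- setdiff(idx, o)
      d2 <- (grid[cand, 1] - grid[o, 1])^2 + (grid[cand, 2] - grid[o, 2])^2
      nb <- cand[d2 <= rad^2]
      if (length(nb) < config$readmit_k) next
      vo <- delta[o, ]
      mo <- sqrt(sum(vo^2))
      floor_nm <- 2 * 16
      # a majority of all measured neighbors inside the diameter must agree
      # in angle and relative magnitude: a coherent locally warped patch
      # qualifies, while an isolated gross vector cannot recruit a majority
      # even if a couple of nearby outliers happen to point the same way
      agree <- vapply(nb, function(b) {
        vb <- delta[b, ]
        mb <- sqrt(sum(vb^2))
        if (mo < floor_nm && mb < floor_nm) return(TRUE)
        if (mb < 1e-9) return(FALSE)
        ang <- acos(pmin(pmax(sum(vo * vb) / (mo * mb + 1e-12), -1), 1)) * 180 / pi
        ang <= config$readmit_angle_deg &&
          abs(mo - mb) / max(mb, floor_nm) <= config$readmit_rel
      }, logical(1))
      if (mean(agree) > 0.5) readmit[o] <- TRUE
    }
  }
  inlier[readmit] <- TRUE
  list(inlier = inlier,
       inlier_fraction = sum(inlier) / max(1, sum(active)),
       readmitted = readmit)
}

#' Replace outlier / unmeasured deltas by rigid MLS interpolation
#'
#' Inlier grid deltas act as MLS controls; every active point that is not an
#' inlier receives the MLS-estimated delta and is tagged for down-weighting.
#'
#' @param delta n x 2 deltas (nm).
#' @param grid n x 2 grid (nm).
#' @param inlier logical inlier mask.
#' @param active logical active mask.
#' @param config [pipeline_config()].
#' @return list: `delta` (complete over active points), `weight` (per grid
#'   point: 1 inlier, `replaced_weight` replaced), `ok`.
#' @export
replace_outliers <- function(delta, grid, inlier, active,
                             config = pipeline_config()) {
  w <- rep(NA_real_, nrow(grid))
  if (sum(inlier) < 2) {
    warning("fewer than 2 inliers; comparison dropped")
    return(list(delta = delta, weight = w, ok = FALSE))
  }
  w[inlier] <- 1
  fill <- which(active & !inlier)
  if (length(fill)) {
    ctrl <- which(inlier)
    q <- mls_rigid(grid[ctrl, , drop = FALSE],
                   grid[ctrl, , drop = FALSE] + delta[ctrl, , drop = FALSE],
                   grid[fill, , drop = FALSE], alpha = config$mls_alpha)
    delta[fill, ] <- q - grid[fill, , drop = FALSE]
    w[fill] <- config$replaced_weight
  }
  list(delta = delta, weight = w, ok = TRUE)
}

#' Affine filter: enforce local rigidity of a vector field
#'
#' Fits the deltas inside the square window centered on every grid point
#' with a full affine and replaces the center delta by the fit's prediction;
#' globally affine fields are fixed points. Windows with fewer than 3 points
#' pass the delta through.
#'
#' @param delta n x 2 deltas (nm).
#' @param grid n x 2 grid (nm).
#' @param box_nm window side length.
#' @param have logical: points carrying a delta.
#' @return filtered n x 2 delta matrix.
#' @export
affine_filter <- function(delta, grid, box_nm, have = NULL) {
  if (is.null(have)) have <- !is.na(delta[, 1])
  out <- delta
  half <- box_nm / 2
  hidx <- which(have)
  for (g in hidx) {
    win <- hidx[abs(grid[hidx, 1] - grid[g, 1]) <= half &
                  abs(grid[hidx, 2] - grid[g, 2]) <= half]
    if (length(win) < 3) next
    A <- tryCatch(fit_affine(grid[win, , drop = FALSE],
                             grid[win, , drop = FALSE] + delta[win, , drop = FALSE],
                             "full"),
                  error = function(e) NULL)
    if (is.null(A)) next
    out[g, ] <- apply_affine(A, grid[g, , drop = FALSE]) - grid[g, ]
  }
  out
}

#' Fine or ultrafine elastic alignment of a section stack
#'
#' Pipeline: measure rotation-swept nxcorr deltas on the masked hex grid for
#' all (i, i +/- n) pairs; RANSAC-quadratic outlier rejection with
#' neighborhood re-admission; rigid-MLS replacement of rejected/unmeasured
#' deltas (down-weighted 0.5); optional affine filtering (fine stage); and
#' the per-grid-point weighted/ridge delta solve with neighbor-distance
#' weights. Returns one destination-to-source warp field per section plus
#' the solved-magnitude distribution.
#'
#' @param sections aligned section images (rough-aligned for fine;
#'   fine-exported for ultrafine).
#' @param pixel_size_nm stack pixel size.
#' @param config [pipeline_config()].
#' @param stage `"fine"` or `"ultrafine"`.
#' @param roi,mask optional grid restriction (see [make_masked_grid()]).
#' @param seed RANSAC seed.
#' @return list of class `fine_alignment`: `u` (n_sections x n_grid x 2 nm,
#'   dest-to-source), `grid`, `active`, `inlier_fractions` (per comparison,
#'   with neighbor offset), `magnitudes_nm` (per-section solved magnitude
#'   vectors), `fields` (post-processing measured fields).
#' @export
fine_align_stack <- function(sections, pixel_size_nm = 16,
                             config = pipeline_config(),
                             stage = c("fine", "ultrafine"),
                             roi = NULL, mask = NULL, seed = 1) {
  stage <- match.arg(stage)
  params <- fine_params(config, stage)
  n_sec <- length(sections)
  grid <- make_masked_grid(dim(sections[[1]]), pixel_size_nm, params$grid_nm,
                           roi = roi, mask = mask, config = config)
  fields <- measure_fine_deltas(sections, grid, params, pixel_size_nm, config)
  infr <- NULL
  for (ci in seq_along(fields$comparisons)) {
    cmp <- fields$comparisons[[ci]]
    det <- detect_outliers(cmp$delta, fields$grid, cmp$valid, fields$active,
                           config, seed = seed + ci)
    rep_ <- replace_outliers(cmp$delta, fields$grid, det$inlier, fields$active,
                             config)
    if (!rep_$ok) { fields$comparisons[[ci]]$weight <- rep(NA_real_, nrow(fields$grid)); next }
    delta <- rep_$delta
    if (params$affine_filter)
      delta <- affine_filter(delta, fields$grid, params$affine_box_nm,
                             have = !is.na(rep_$weight))
    fields$comparisons[[ci]]$delta <- delta
    fields$comparisons[[ci]]$weight <- rep_$weight
    fields$comparisons[[ci]]$valid <- !is.na(rep_$weight)
    infr <- rbind(infr, data.frame(i = cmp$i, j = cmp$j, n = cmp$j - cmp$i,
                                   inlier_fraction = det$inlier_fraction))
  }
  wfn <- function(n_off) params$neighbor_weights[min(n_off, length(params$neighbor_weights))]
  resolved <- solve_grid_deltas(fields, n_sec, config,
                                weights_fn = wfn, l2 = params$l2,
                                detrend = FALSE)
  mags <- lapply(seq_len(n_sec), function(i)
    sqrt(rowSums(resolved$u[i, , , drop = TRUE]^2)))
  structure(list(u = resolved$u, grid = fields$grid, active = fields$active,
                 inlier_fractions = infr, magnitudes_nm = mags,
                 fields = fields, params = params,
                 pixel_size_nm = pixel_size_nm),
            class = "fine_alignment")
}
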