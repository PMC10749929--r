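# 2D section montaging: hexagonal neighbor graph, nxcorr tile deltas,
# two-pass outlier detection with median replacement, the tile-coordinate
# least-squares solve, and feathered mosaic rendering.

#' Build the tile neighbor graph of a section
#'
#' Intra-mFOV edges connect lattice-adjacent tiles (each interior tile has 6
#' neighbors in the hexagonal layout); inter-mFOV edges connect facing
#' perimeter tiles of adjacent mFOVs within a distance cutoff. Each
#' unordered tile pair appears once, directed from the lower to the higher
#' tile index, with `delta = coord[dst] - coord[src]`.
#'
#' @param tiles list of tiles (`image`, `mfov_id`, `beam_id`, `nominal_xy`).
#' @param layout [hex_layout()] of the acquisition.
#' @return data.frame: `src`, `dst`, `class` ("intra"/"inter"),
#'   `nominal_dx`, `nominal_dy` (nm).
#' @export
build_neighbor_graph <- function(tiles, layout) {
  n <- length(tiles)
  xy <- t(vapply(tiles, function(t) t$nominal_xy, numeric(2)))
  mf <- vapply(tiles, function(t) t$mfov_id, numeric(1))
  s <- layout$spacing_nm
  tile_w <- layout$tile_shape_px[2] * layout$pixel_size_nm
  edges <- list()
  for (i in seq_len(n - 1)) {
    dx <- xy[(i + 1):n, 1] - xy[i, 1]
    dy <- xy[(i + 1):n, 2] - xy[i, 2]
    d <- sqrt(dx^2 + dy^2)
    same <- mf[(i + 1):n] == mf[i]
    near <- (same & d < 1.25 * s) | (!same & d < 1.05 * tile_w)
    js <- which(near)
    if (!length(js)) next
    edges[[length(edges) + 1]] <- data.frame(
      src = i, dst = i + js,
      class = ifelse(same[js], "intra", "inter"),
      nominal_dx = dx[js], nominal_dy = dy[js])
  }
  if (!length(edges)) return(data.frame(src = integer(), dst = integer(),
                                        class = character(),
                                        nominal_dx = numeric(), nominal_dy = numeric()))
  do.call(rbind, edges)
}

# the half-by-half crop of `img` adjacent to the neighbor in direction d
# (nm); returns the crop and its center offset (px) from the tile center
quarter_crop <- function(img, d) {
  h <- nrow(img); w <- ncol(img)
  hw <- w %/% 2; hh <- h %/% 2
  eps_x <- 1e-6 * max(abs(d[1]), 1)
  xs <- if (d[1] > eps_x) (w - hw + 1):w else if (d[1] < -eps_x) 1:hw else
    (floor(w / 4) + 1):(floor(w / 4) + hw)
  ys <- if (d[2] > eps_x) (h - hh + 1):h else if (d[2] < -eps_x) 1:hh else
    (floor(h / 4) + 1):(floor(h / 4) + hh)
  list(crop = img[ys, xs, drop = FALSE],
       center_off_px = c(mean(xs) - (w + 1) / 2, mean(ys) - (h + 1) / 2))
}

#' Measure tile-to-tile deltas with nxcorr template matching
#'
#' For each edge, the full destination tile is the main image and the
#' quadrant of the source tile nearest the destination is the template
#' (both preprocessed). The matched template position yields the measured
#' center-to-center delta in nm. Edges whose raw source crop or destination
#' tile has grayscale variance below the configured floor are flagged
#' outliers immediately.
#'
#' @param tiles tile list.
#' @param edges output of [build_neighbor_graph()].
#' @param config [pipeline_config()].
#' @return `edges` with columns `dx`, `dy` (measured, nm), `peak`,
#'   `var_outlier`.
#' @export
measure_deltas <- function(tiles, edges, config = pipeline_config()) {
  ps <- tiles[[1]]$pixel_size_nm
  pp <- lapply(tiles, function(t) preprocess_image(t$image, ps, config))
  m <- nrow(edges)
  edges$dx <- NA_real_; edges$dy <- NA_real_
  edges$peak <- NA_real_; edges$var_outlier <- FALSE
  for (e in seq_len(m)) {
    i <- edges$src[e]; j <- edges$dst[e]
    d <- c(edges$nominal_dx[e], edges$nominal_dy[e])
    qc_raw <- quarter_crop(tiles[[i]]$image, d)
    if (stats::var(as.vector(qc_raw$crop)) < config$variance_floor ||
        !pp[[j]]$valid || !pp[[i]]$valid) {
      edges$var_outlier[e] <- TRUE
      next
    }
    qc <- quarter_crop(pp[[i]]$image, d)
    r <- nxcorr_match(pp[[j]]$image, qc$crop, ps, mode = "full")
    if (!r$valid) { edges$var_outlier[e] <- TRUE; next }
    # same content: src_center + crop_off = dst_center + delta_t
    dd <- (qc$center_off_px - r$delta_px) * ps
    edges$dx[e] <- dd[1]; edges$dy[e] <- dd[2]
    edges$peak[e] <- r$peak_value
  }
  edges
}

#' Two-pass outlier detection with median replacement
#'
#' Pass 1 flags deltas outside a box tolerance around the nominal
#' (acquisition-expected) delta, with separate intra-/inter-mFOV box sizes.
#' Per neighbor direction, median deltas are computed over the surviving
#' edges of the mFOV series; pass 2 flags deltas outside the tighter box
#' around the median. All flagged edges receive the direction median as a
#' replacement delta (falling back to the nominal delta, with a warning,
#' when a direction has no survivors) and are down-weighted.
#'
#' @param edges measured edges (from [measure_deltas()]).
#' @param config [pipeline_config()].
#' @return `edges` with `outlier` (pass-1 or pass-2 or variance flag),
#'   `pass1`, `pass2`, `replaced`, updated `dx`/`dy`, and `weight`.
#' @export
outlier_two_pass <- function(edges, config = pipeline_config()) {
  intra <- edges$class == "intra"
  dev_x <- abs(edges$dx - edges$nominal_dx)
  dev_y <- abs(edges$dy - edges$nominal_dy)
  t1x <- ifelse(intra, config$tol_pass1_intra_nm[1], config$tol_pass1_inter_nm[1]) / 2
  t1y <- ifelse(intra, config$tol_pass1_intra_nm[2], config$tol_pass1_inter_nm[2]) / 2
  edges$pass1 <- edges$var_outlier | is.na(edges$dx) | dev_x > t1x | dev_y > t1y
  # direction key: rounded nominal delta (identical across the mFOV series
  # for the same lattice direction)
  key <- paste(edges$class, round(edges$nominal_dx / 10), round(edges$nominal_dy / 10))
  med_x <- stats::ave(ifelse(edges$pass1, NA, edges$dx), key,
                      FUN = function(v) stats::median(v, na.rm = TRUE))
  med_y <- stats::ave(ifelse(edges$pass1, NA, edges$dy), key,
                      FUN = function(v) stats::median(v, na.rm = TRUE))
  no_med <- is.na(med_x) | is.na(med_y)
  if (any(no_med)) {
    warning("direction(s) with no surviving deltas; falling back to nominal overlap delta")
    med_x[no_med] <- edges$nominal_dx[no_med]
    med_y[no_med] <- edges$nominal_dy[no_med]
  }
  t2x <- ifelse(intra, config$tol_pass2_intra_nm[1], config$tol_pass2_inter_nm[1]) / 2
  t2y <- ifelse(intra, config$tol_pass2_intra_nm[2], config$tol_pass2_inter_nm[2]) / 2
  edges$pass2 <- !edges$pass1 &
    (abs(edges$dx - med_x) > t2x | abs(edges$dy - med_y) > t2y)
  edges$outlier <- edges$pass1 | edges$pass2
  edges$replaced <- edges$outlier
  edges$dx[edges$outlier] <- med_x[edges$outlier]
  edges$dy[edges$outlier] <- med_y[edges$outlier]
  edges$weight <- ifelse(edges$replaced, config$replaced_weight_2d, 1)
  edges
}

#' Solve global tile coordinates for one section
#'
#' Feeds the edge deltas into the difference-system solver with replaced
#' edges down-weighted; the offset bias is removed by mean subtraction so
#' the coordinate origin sits near the mosaic center.
#'
#' @param edges processed edges (from [outlier_two_pass()]).
#' @param n_tiles number of tiles.
#' @return list: `coords_nm` (n x 2), `residual_nm` (per edge, Euclidean),
#'   `solved` (full `solved_coords`).
#' @export
solve_section <- function(edges, n_tiles) {
  g <- delta_graph(n_tiles, edges$src, edges$dst,
                   cbind(edges$dx, edges$dy),
                   weight = edges$weight,
                   outlier = edges$outlier, replaced = edges$replaced)
  s <- solve_deltas(g)
  list(coords_nm = s$coords,
       residual_nm = sqrt(rowSums(s$residuals^2)),
       solved = s)
}

# per-tile feather weight map: linear ramps from each tile border, with the
# ramp length chosen per side by the class of the nearest neighbor beyond it
feather_weights <- function(th, tw, ramp_px_side) {
  g <- coord_grid(th, tw)
  wx <- pmin((g$x + 0.5) / ramp_px_side["left"], (tw - 0.5 - g$x) / ramp_px_side["right"])
  wy <- pmin((g$y + 0.5) / ramp_px_side["top"], (th - 0.5 - g$y) / ramp_px_side["bottom"])
  pmax(pmin(wx, wy, 1), 1e-6)
}

#' Render a feathered section mosaic
#'
#' Places corrected tiles at the solved coordinates and blends overlaps with
#' linear feather ramps (0.5 um within an mFOV, 3 um between mFOVs at the
#' production scale). Blend weights are normalized so they sum to one at
#' every covered output pixel; away from overlaps the output equals the
#' single contributing corrected tile.
#'
#' @param tiles tile list.
#' @param coords_nm solved tile-center coordinates (n x 2, nm).
#' @param edges neighbor edges (used to pick per-side ramp classes); NULL
#'   uses intra ramps everywhere.
#' @param corrections optional [beam_corrections()] output to apply.
#' @param config [pipeline_config()].
#' @return list: `image`, `weight` (coverage), `origin_nm` (world coordinate
#'   of output pixel (0,0) center).
#' @export
render_montage <- function(tiles, coords_nm, edges = NULL, corrections = NULL,
                           config = pipeline_config()) {
  ps <- tiles[[1]]$pixel_size_nm
  th <- nrow(tiles[[1]]$image); tw <- ncol(tiles[[1]]$image)
  n <- length(tiles)
  # round the top-left placement (integer-valued for exact solutions even
  # when tile centers fall on half pixels)
  tlx <- round(coords_nm[, 1] / ps - (tw - 1) / 2)
  tly <- round(coords_nm[, 2] / ps - (th - 1) / 2)
  x0 <- min(tlx); y0 <- min(tly)
  W <- max(tlx) - x0 + tw
  H <- max(tly) - y0 + th
  num <- matrix(0, H, W); den <- matrix(0, H, W)
  ramp_intra <- max(1, config$feather_intra_nm / ps)
  ramp_inter <- max(1, config$feather_inter_nm / ps)
  for (i in seq_len(n)) {
    img <- apply_corrections(tiles[[i]], corrections, tile_index = i)
    sides <- c(left = ramp_intra, right = ramp_intra,
               top = ramp_intra, bottom = ramp_intra)
    if (!is.null(edges) && nrow(edges)) {
      ei <- which(edges$src == i | edges$dst == i)
      for (e in ei) {
        if (edges$class[e] != "inter") next
        d <- c(edges$nominal_dx[e], edges$nominal_dy[e])
        if (edges$dst[e] == i) d <- -d
        if (abs(d[1]) >= abs(d[2])) sides[if (d[1] > 0) "right" else "left"] <- ramp_inter
        else sides[if (d[2] > 0) "bottom" else "top"] <- ramp_inter
      }
    }
    wmap <- feather_weights(th, tw, sides)
    ys <- tly[i] - y0 + seq_len(th); xs <- tlx[i] - x0 + seq_len(tw)
    num[ys, xs] <- num[ys, xs] + wmap * img
    den[ys, xs] <- den[ys, xs] + wmap
  }
  out <- num
  cov <- den > 0
  out[cov] <- num[cov] / den[cov]
  list(image = out, weight = den, origin_nm = c(x0, y0) * ps)
}

#' Montage one section end to end
#'
#' Convenience driver: neighbor graph, delta measurement, two-pass outlier
#' handling, coordinate solve and feathered rendering.
#'
#' @param tiles tile list (one section).
#' @param layout [hex_layout()].
#' @param corrections optional beam corrections.
#' @param config [pipeline_config()].
#' @return list: `image`, `origin_nm`, `coords_nm`, `edges`, `residual_nm`.
#' @export
montage_section <- function(tiles, layout, corrections = NULL,
                            config = pipeline_config()) {
  edges <- build_neighbor_graph(tiles, layout)
  edges <- measure_deltas(tiles, edges, config)
  edges <- outlier_two_pass(edges, config)
  sol <- solve_section(edges, length(tiles))
  mon <- render_montage(tiles, sol$coords_nm, edges, corrections, config)
  list(image = mon$image, origin_nm = mon$origin_nm, weight = mon$weight,
       coords_nm = sol$coords_nm, edges = edges, residual_nm = sol$residual_nm)
}
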