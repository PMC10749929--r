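# Two-pass per-beam gradient and brightness correction via mFOV tile
# averaging, plus the sub-tile histogram-shift LSS refinement with MST
# connectivity and per-tile polynomial brightness surfaces.

# inlier heuristics: mode inside section-histogram quantile range, and no
# out-of-range connected component larger than the configured fraction
tile_inlier <- function(img, lo, hi, max_frac) {
  m <- hist_mode(img)
  if (m < lo || m > hi) return(list(ok = FALSE, reason = "mode out of range"))
  for (mask in list(img < lo, img > hi)) {
    if (!any(mask)) next
    lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
    if (max(lab) > 0) {
      sizes <- tabulate(as.integer(lab[lab > 0]))
      if (max(sizes) > max_frac * length(img))
        return(list(ok = FALSE, reason = "large out-of-range component"))
    }
  }
  list(ok = TRUE, reason = NA_character_)
}

#' Average tiles per beam position with outlier rejection
#'
#' Tiles sharing the same intra-mFOV beam position are averaged into a mean
#' tile per beam. Tiles are rejected when their histogram mode falls outside
#' a quantile range of the overall section histogram, or when they contain a
#' connected out-of-range component covering more than the configured
#' fraction of the tile (e.g. bare-wafer or heavily stained regions).
#'
#' @param tiles tile list (one section); images may be pre-corrected.
#' @param config [pipeline_config()].
#' @return list: `mean_tiles` (per beam id; NULL where no inliers),
#'   `rejections` (data.frame tile/beam/reason), `range` (lo, hi).
#' @export
average_beam_tiles <- function(tiles, config = pipeline_config()) {
  beams <- vapply(tiles, function(t) t$beam_id, numeric(1))
  all_v <- unlist(lapply(tiles, function(t) as.vector(t$image)))
  qs <- stats::quantile(all_v, config$reject_quantiles, names = FALSE)
  lo <- qs[1]; hi <- qs[2]
  B <- max(beams)
  acc <- vector("list", B); cnt <- integer(B)
  rej <- list()
  for (i in seq_along(tiles)) {
    ok <- tile_inlier(tiles[[i]]$image, lo, hi, config$large_component_frac)
    if (!ok$ok) {
      rej[[length(rej) + 1]] <- data.frame(tile = i, beam = beams[i], reason = ok$reason)
      next
    }
    b <- beams[i]
    acc[[b]] <- if (is.null(acc[[b]])) tiles[[i]]$image else acc[[b]] + tiles[[i]]$image
    cnt[b] <- cnt[b] + 1L
  }
  mean_tiles <- vector("list", B)
  for (b in seq_len(B)) {
    if (cnt[b] == 0L) {
      warning("beam ", b, " has no inlier tiles; correction falls back to identity")
      next
    }
    mean_tiles[[b]] <- acc[[b]] / cnt[b]
  }
  list(mean_tiles = mean_tiles,
       rejections = if (length(rej)) do.call(rbind, rej) else
         data.frame(tile = integer(), beam = integer(), reason = character()),
       range = c(lo, hi))
}

#' First-pass gradient correction factors
#'
#' Box-filters each per-beam mean tile (1 x 1 um box at production scale)
#' and divides by its mode, producing a multiplicative gradient scale raster
#' per beam; corrected tiles are divided by the raster.
#'
#' @param mean_tiles per-beam mean tiles (from [average_beam_tiles()]).
#' @param pixel_size_nm tile pixel size.
#' @param config [pipeline_config()].
#' @return list of scale rasters (identity matrix of ones where the beam had
#'   no mean tile).
#' @export
gradient_pass <- function(mean_tiles, pixel_size_nm = 16, config = pipeline_config()) {
  box_px <- max(1, round(config$gradient_box_nm / pixel_size_nm))
  lapply(mean_tiles, function(mt) {
    if (is.null(mt)) return(NULL)
    sm <- box_filter(mt, box_px)
    md <- hist_mode(sm)
    if (md <= 0) stop("zero mode in gradient pass")
    sm / md
  })
}

#' Second-pass brightness offsets
#'
#' Takes per-beam mean tiles computed from gradient-corrected tiles; the
#' offset for each beam is its mean-tile mode minus the mean of all modes
#' (one integer gray value per beam, zero-mean across beams).
#'
#' @param mean_tiles per-beam mean tiles of gradient-corrected tiles.
#' @return integer offset vector (0 where no mean tile).
#' @export
brightness_pass <- function(mean_tiles) {
  modes <- vapply(mean_tiles, function(mt)
    if (is.null(mt)) NA_real_ else hist_mode(mt), numeric(1))
  off <- modes - mean(modes, na.rm = TRUE)
  off[is.na(off)] <- 0
  round(off)
}

# cross-correlate standardized histograms over lags; returns best lag
# (brightness dst - src) and correlation distance per pair, computed in
# batch via FFT
hist_lag_table <- function(H, max_lag = 64L) {
  nb <- nrow(H); S <- ncol(H)
  Hs <- scale(H)                        # standardize each histogram
  bad <- !is.finite(colSums(Hs))
  Hs[, bad] <- 0
  n <- 2L * nb
  P <- rbind(Hs, matrix(0, nb, S))
  F <- stats::mvfft(P)
  lags <- c(0:max_lag, (n - max_lag):(n - 1)) # +0..max, then -max..-1
  lag_val <- c(0:max_lag, -(max_lag:1))
  out <- NULL
  for (i in seq_len(S - 1)) {
    cc <- Re(stats::mvfft(Conj(F[, i]) * F[, (i + 1):S, drop = FALSE],
                          inverse = TRUE)) / n / (nb - 1)
    cc <- cc[lags + 1L, , drop = FALSE]
    best <- apply(cc, 2, which.max)
    out <- rbind(out, data.frame(
      src = i, dst = (i + 1):S,
      lag = lag_val[best],
      dist = 1 - cc[cbind(best, seq_len(ncol(cc)))]))
  }
  out$dist[!is.finite(out$dist)] <- 2
  if (any(bad)) out$dist[out$src %in% which(bad) | out$dst %in% which(bad)] <- 2
  out
}

#' Sub-tile histogram-shift brightness refinement
#'
#' Splits every tile into a grid of sub-tiles (3 x 3 by default), compares
#' all pairwise sub-tile histograms with ZNCC over gray-level lags, and
#' builds the histogram-shift difference system from the top-n best-matching
#' neighbors per sub-tile (restricted to pairs below the correlation-distance
#' ceiling) plus the minimum-spanning-tree edges of the full
#' correlation-distance graph, which guarantee a single connected component
#' even where they exceed that ceiling.
#' The solved per-sub-tile offsets (mean removed) are fit per tile with a 2D
#' polynomial surface applied additively. Groups larger than the configured
#' size are solved independently.
#'
#' @param tiles tile list whose images already carry the two-pass correction.
#' @param config [pipeline_config()].
#' @return list: `surfaces` (per tile: coefficient vector of the polynomial
#'   in normalized tile coordinates), `subtile_offsets` (matrix tiles x
#'   sub-tiles), `grid` (sub-tile grid dims).
#' @export
subtile_histogram_refine <- function(tiles, config = pipeline_config()) {
  gr <- config$subtile_grid
  n_t <- length(tiles)
  th <- nrow(tiles[[1]]$image); tw <- ncol(tiles[[1]]$image)
  ys <- round(seq(0, th, length.out = gr[1] + 1))
  xs <- round(seq(0, tw, length.out = gr[2] + 1))
  S_per <- gr[1] * gr[2]
  S <- n_t * S_per
  H <- matrix(0, config$hist_bins, S)
  centers <- matrix(0, S, 2)             # normalized tile coords in [-1, 1]
  k <- 0L
  for (i in seq_len(n_t)) for (r in seq_len(gr[1])) for (c in seq_len(gr[2])) {
    k <- k + 1L
    sub <- tiles[[i]]$image[(ys[r] + 1):ys[r + 1], (xs[c] + 1):xs[c + 1]]
    H[, k] <- hist256(sub) / length(sub)
    centers[k, ] <- c((xs[c] + xs[c + 1]) / tw - 1, (ys[r] + ys[r + 1]) / th - 1)
  }
  groups <- if (S > config$subtile_group_size) {
    ng <- ceiling(S / config$subtile_group_size)
    split(seq_len(S), rep(seq_len(ng), length.out = S))
  } else list(seq_len(S))
  offsets <- numeric(S)
  for (gidx in groups) {
    tab <- hist_lag_table(H[, gidx, drop = FALSE])
    sg <- length(gidx)
    # top-n neighbors per sub-tile, gated by the minimum correlation
    # distance for two histograms to count as neighbors; MST edges are
    # added below even when they exceed the threshold
    keep <- rep(FALSE, nrow(tab))
    for (v in seq_len(sg)) {
      rows <- which(tab$src == v | tab$dst == v)
      rows <- rows[order(tab$dist[rows])]
      rows <- rows[tab$dist[rows] <= config$hist_max_dist]
      keep[utils::head(rows, config$hist_top_n)] <- TRUE
    }
    # MST over the full correlation-distance graph
    g <- igraph::graph_from_data_frame(
      data.frame(from = tab$src, to = tab$dst, weight = tab$dist + 1e-9),
      directed = FALSE, vertices = data.frame(name = seq_len(sg)))
    mst <- igraph::mst(g)
    me <- igraph::as_edgelist(mst)
    mkey <- paste(pmin(as.integer(me[, 1]), as.integer(me[, 2])),
                  pmax(as.integer(me[, 1]), as.integer(me[, 2])))
    tkey <- paste(pmin(tab$src, tab$dst), pmax(tab$src, tab$dst))
    keep <- keep | tkey %in% mkey
    sub <- tab[keep, ]
    gph <- delta_graph(sg, sub$src, sub$dst, matrix(sub$lag, ncol = 1))
    offsets[gidx] <- solve_deltas(gph)$coords[, 1]
  }
  # per-tile quadratic surface over sub-tile centers
  surfaces <- vector("list", n_t)
  basis <- function(x, y) cbind(1, x, y, x^2, x * y, y^2)
  for (i in seq_len(n_t)) {
    idx <- ((i - 1) * S_per + 1):(i * S_per)
    X <- basis(centers[idx, 1], centers[idx, 2])
    surfaces[[i]] <- qr.coef(qr(X), offsets[idx])
  }
  list(surfaces = surfaces,
       subtile_offsets = matrix(offsets, n_t, S_per, byrow = TRUE),
       grid = gr)
}

# evaluate a tile's polynomial brightness surface as a raster
surface_raster <- function(coef, th, tw) {
  g <- coord_grid(th, tw)
  x <- as.vector(2 * (g$x + 0.5) / tw - 1)
  y <- as.vector(2 * (g$y + 0.5) / th - 1)
  matrix(cbind(1, x, y, x^2, x * y, y^2) %*% coef, th, tw)
}

#' Compute the full set of beam corrections for a section
#'
#' Runs the two-pass gradient/brightness estimation and the sub-tile
#' histogram refinement. The correction path needs no solved tile positions
#' and may run independently of the coordinate alignment.
#'
#' @param tiles tile list (one section).
#' @param config [pipeline_config()].
#' @return list of class `beam_corrections`: `gradient` (per beam),
#'   `offset` (per beam), `surfaces` (per tile), `rejections`.
#' @export
beam_corrections <- function(tiles, config = pipeline_config()) {
  ps <- tiles[[1]]$pixel_size_nm
  av1 <- average_beam_tiles(tiles, config)
  grad <- gradient_pass(av1$mean_tiles, ps, config)
  t1 <- lapply(tiles, function(t) {
    g <- grad[[t$beam_id]]
    if (!is.null(g)) t$image <- t$image / g
    t
  })
  av2 <- average_beam_tiles(t1, config)
  off <- brightness_pass(av2$mean_tiles)
  t2 <- lapply(t1, function(t) { t$image <- t$image - off[t$beam_id]; t })
  refine <- subtile_histogram_refine(t2, config)
  structure(list(gradient = grad, offset = off, surfaces = refine$surfaces,
                 subtile_offsets = refine$subtile_offsets,
                 rejections = av1$rejections),
            class = "beam_corrections")
}

#' Apply beam corrections to one tile
#'
#' Order: divide by the beam gradient raster, subtract the beam brightness
#' offset, subtract the tile's polynomial brightness surface.
#'
#' @param tile a tile (needs `image`, `beam_id`).
#' @param corrections [beam_corrections()] output, or NULL for no-op.
#' @param tile_index index of the tile (for its surface); NULL skips the
#'   surface term.
#' @return corrected image matrix (float).
#' @export
apply_corrections <- function(tile, corrections, tile_index = NULL) {
  img <- tile$image
  if (is.null(corrections)) return(img)
  g <- corrections$gradient[[tile$beam_id]]
  if (!is.null(g)) img <- img / g
  img <- img - corrections$offset[tile$beam_id]
  if (!is.null(tile_index) && !is.null(corrections$surfaces[[tile_index]]))
    img <- img - surface_raster(corrections$surfaces[[tile_index]],
                                nrow(img), ncol(img))
  img
}
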