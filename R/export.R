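# Blockwise final rendering: inverse-transform composition from rough-bbox
# coordinates back to source image space, bilinear densification of warp
# fields, and remap-based warping with seam-free block assembly.

#' Interpolate a hexagonal vector field at arbitrary points
#'
#' Piecewise-linear interpolation adapted to the offset hex lattice: linear
#' interpolation along each hex row in x, then linear blending between the
#' two bracketing rows in y. Exact at grid points and exact for fields that
#' are linear in (x, y); queries beyond the grid bounding box are clamped to
#' the border values (callers crop to the grid bbox to avoid extrapolation).
#'
#' @param grid n x 2 hex grid positions (nm).
#' @param values n x m field values.
#' @param qx,qy query coordinates (nm).
#' @return length(qx) x m matrix.
#' @export
hex_field_interp <- function(grid, values, qx, qy) {
  values <- as.matrix(values)
  rows_y <- sort(unique(round(grid[, 2], 6)))
  nr <- length(rows_y)
  row_of <- match(round(grid[, 2], 6), rows_y)
  row_pts <- split(seq_len(nrow(grid)), row_of)
  m <- ncol(values)
  out <- matrix(NA_real_, length(qx), m)
  interp_row <- function(r, x) {
    idx <- row_pts[[r]]
    ox <- order(grid[idx, 1])
    xs <- grid[idx[ox], 1]
    n <- length(xs)
    sapply(seq_len(m), function(k) {
      if (n == 1) return(rep(values[idx, k], length(x)))
      v <- values[idx[ox], k]
      y <- stats::approx(xs, v, xout = x, rule = 2)$y
      # linear extension beyond the row ends keeps staggered hex rows
      # consistent (exact for linear fields)
      lo <- x < xs[1]; hi <- x > xs[n]
      y[lo] <- v[1] + (v[2] - v[1]) / (xs[2] - xs[1]) * (x[lo] - xs[1])
      y[hi] <- v[n] + (v[n] - v[n - 1]) / (xs[n] - xs[n - 1]) * (x[hi] - xs[n])
      y
    })
  }
  ri <- findInterval(qy, rows_y)
  ri[ri < 1] <- 1; ri[ri > nr - 1] <- max(nr - 1, 1)
  for (r in sort(unique(ri))) {
    sel <- which(ri == r)
    v0 <- matrix(interp_row(r, qx[sel]), ncol = m)
    if (nr == 1) { out[sel, ] <- v0; next }
    v1 <- matrix(interp_row(r + 1, qx[sel]), ncol = m)
    t <- (qy[sel] - rows_y[r]) / (rows_y[r + 1] - rows_y[r])
    t <- pmin(pmax(t, 0), 1)
    out[sel, ] <- v0 * (1 - t) + v1 * t
  }
  out
}

#' Densify a warp field over a pixel block
#'
#' @param grid,u hex grid (nm) and displacements (n x 2 nm).
#' @param xs,ys 0-based pixel coordinate vectors of the block.
#' @param pixel_size_nm output pixel size.
#' @return list of matrices `ux`, `uy` (nm) of dim (length(ys),
#'   length(xs)).
#' @export
densify_field <- function(grid, u, xs, ys, pixel_size_nm = 16) {
  g <- expand.grid(x = xs, y = ys)
  v <- hex_field_interp(grid, u, g$x * pixel_size_nm, g$y * pixel_size_nm)
  list(ux = matrix(v[, 1], length(ys), length(xs), byrow = TRUE),
       uy = matrix(v[, 2], length(ys), length(xs), byrow = TRUE))
}

#' Assemble a transform chain
#'
#' @param coarse,rough per-section lists of destination-to-source
#'   [affine2d()] transforms (or NULL stage).
#' @param fine,ultra optional `fine_alignment` objects.
#' @param bbox_px c(h, w) rough bounding box.
#' @param pixel_size_nm working pixel size of the chain.
#' @return list of class `transform_chain`.
#' @export
transform_chain <- function(coarse = NULL, rough = NULL, fine = NULL,
                            ultra = NULL, bbox_px, pixel_size_nm = 16) {
  n <- max(length(coarse), length(rough),
           if (!is.null(fine)) dim(fine$u)[1] else 0L,
           if (!is.null(ultra)) dim(ultra$u)[1] else 0L)
  for (st in list(coarse, rough))
    if (!is.null(st) && length(st) != n)
      stop("stages must cover the same number of sections")
  structure(list(coarse = coarse, rough = rough, fine = fine, ultra = ultra,
                 bbox_px = bbox_px, pixel_size_nm = pixel_size_nm,
                 n_sections = n),
            class = "transform_chain")
}

#' Invert a transform chain at output coordinates
#'
#' Maps rough-bbox destination coordinates back to source-image coordinates
#' by applying the stage inverses in reverse measurement order: ultrafine
#' warp, fine warp, rough affine, coarse affine. Elastic fields are stored
#' as destination-to-source lookups, so "inversion" is direct application in
#' remap order; affines are applied as the destination-to-source transforms
#' they were fitted as.
#'
#' @param chain `transform_chain`.
#' @param i section index.
#' @param qx_nm,qy_nm destination coordinates (nm, rough-bbox frame).
#' @param stages character subset of stages to apply (default all present).
#' @return n x 2 matrix of source coordinates (nm).
#' @export
invert_chain <- function(chain, i, qx_nm, qy_nm,
                         stages = c("ultra", "fine", "rough", "coarse")) {
  p <- cbind(qx_nm, qy_nm)
  if ("ultra" %in% stages && !is.null(chain$ultra))
    p <- p + hex_field_interp(chain$ultra$grid, chain$ultra$u[i, , ], p[, 1], p[, 2])
  if ("fine" %in% stages && !is.null(chain$fine))
    p <- p + hex_field_interp(chain$fine$grid, chain$fine$u[i, , ], p[, 1], p[, 2])
  if ("rough" %in% stages && !is.null(chain$rough))
    p <- apply_affine(chain$rough[[i]], p)
  if ("coarse" %in% stages && !is.null(chain$coarse))
    p <- apply_affine(chain$coarse[[i]], p)
  p
}

#' Export plan
#'
#' @param block_grid c(nx, ny) blocks (production: 4 x 4 at 16 nm, 16 x 16
#'   at 4 nm).
#' @param overlap_px block overlap (default 8).
#' @param pixel_size_nm output pixel size.
#' @param crop_to_grid crop the output to the warp-grid bounding box to
#'   avoid field extrapolation.
#' @return list of class `export_plan`.
#' @export
export_plan <- function(block_grid = c(4, 4), overlap_px = 8,
                        pixel_size_nm = 16, crop_to_grid = FALSE) {
  stopifnot(overlap_px >= 0)
  structure(list(block_grid = block_grid, overlap_px = overlap_px,
                 pixel_size_nm = pixel_size_nm, crop_to_grid = crop_to_grid),
            class = "export_plan")
}

#' Export one section through the inverse transform chain
#'
#' Renders the aligned section blockwise: each block's destination pixel
#' lattice is pushed through [invert_chain()], the source image is sampled
#' bilinearly, and blocks are assembled after trimming the overlap. The
#' assembled output is identical to a whole-image export on all pixels.
#'
#' @param source source image for the remap (the 2D-aligned unoriented
#'   section for a full-chain export; the fine-aligned export when only the
#'   ultrafine stage is inverted).
#' @param chain `transform_chain`.
#' @param i section index.
#' @param plan [export_plan()].
#' @param stages stages to invert (see [invert_chain()]).
#' @return list: `image`, `mask` (TRUE where source pixels existed).
#' @export
export_section <- function(source, chain, i, plan = export_plan(),
                           stages = c("ultra", "fine", "rough", "coarse")) {
  ps <- plan$pixel_size_nm
  scale <- chain$pixel_size_nm / ps
  H <- floor((chain$bbox_px[1] - 1) * scale) + 1
  W <- floor((chain$bbox_px[2] - 1) * scale) + 1
  x0 <- 0; y0 <- 0
  if (plan$crop_to_grid) {
    gsrc <- if (!is.null(chain$fine)) chain$fine else chain$ultra
    if (!is.null(gsrc)) {
      act <- if (any(gsrc$active)) gsrc$active else rep(TRUE, nrow(gsrc$grid))
      bb <- apply(gsrc$grid[act, , drop = FALSE], 2, range) / ps
      x0 <- ceiling(bb[1, 1]); y0 <- ceiling(bb[1, 2])
      W <- floor(bb[2, 1]) - x0 + 1; H <- floor(bb[2, 2]) - y0 + 1
    }
  }
  out <- matrix(0, H, W); msk <- matrix(FALSE, H, W)
  nbx <- plan$block_grid[1]; nby <- plan$block_grid[2]
  bx <- ceiling(W / nbx); by <- ceiling(H / nby)
  for (ix in seq_len(nbx)) for (iy in seq_len(nby)) {
    cx0 <- (ix - 1) * bx; cx1 <- min(ix * bx, W) - 1
    cy0 <- (iy - 1) * by; cy1 <- min(iy * by, H) - 1
    if (cx1 < cx0 || cy1 < cy0) next
    ex0 <- max(0, cx0 - plan$overlap_px); ex1 <- min(W - 1, cx1 + plan$overlap_px)
    ey0 <- max(0, cy0 - plan$overlap_px); ey1 <- min(H - 1, cy1 + plan$overlap_px)
    xs <- ex0:ex1; ys <- ey0:ey1
    gg <- expand.grid(x = xs + x0, y = ys + y0)
    src <- invert_chain(chain, i, gg$x * ps, gg$y * ps, stages = stages)
    rm <- remap_image(source,
                      matrix(src[, 1], length(ys), length(xs), byrow = TRUE) /
                        chain$pixel_size_nm * 1,
                      matrix(src[, 2], length(ys), length(xs), byrow = TRUE) /
                        chain$pixel_size_nm * 1,
                      fill = 0)
    # source sampling happens at the source image's own pixel size
    kr <- (cy0:cy1) - ey0 + 1; kc <- (cx0:cx1) - ex0 + 1
    out[cy0:cy1 + 1, cx0:cx1 + 1] <- rm$image[kr, kc]
    msk[cy0:cy1 + 1, cx0:cx1 + 1] <- rm$mask[kr, kc]
  }
  list(image = out, mask = msk, origin_px = c(x0, y0))
}

#' Export a whole stack
#'
#' @param sources list of source images (2D-aligned sections).
#' @param chain `transform_chain`.
#' @param plan [export_plan()].
#' @param stages stages to invert.
#' @return list of exported section images.
#' @export
export_stack <- function(sources, chain, plan = export_plan(),
                         stages = c("ultra", "fine", "rough", "coarse")) {
  lapply(seq_along(sources), function(i)
    export_section(sources[[i]], chain, i, plan, stages)$image)
}
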