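# Affine fitting at several constraint levels, unique decomposition,
# seeded RANSAC and rigid moving-least-squares deformation. Conventions:
# points are N x 2 matrices (x, y) in nm; transforms act on column vectors,
# y = linear %*% x + translation; positive angles rotate x toward y
# (counter-clockwise in a y-down pixel frame when viewed with y up).

#' 2D affine transform
#'
#' @param linear 2x2 matrix.
#' @param translation length-2 numeric.
#' @return object of class `affine2d`.
#' @export
affine2d <- function(linear = diag(2), translation = c(0, 0)) {
  linear <- matrix(as.numeric(linear), 2, 2)
  structure(list(linear = linear, translation = as.numeric(translation)),
            class = "affine2d")
}

#' Apply an affine transform to points
#' @param A `affine2d`. @param pts N x 2 matrix.
#' @return N x 2 matrix.
#' @export
apply_affine <- function(A, pts) {
  pts <- matrix(pts, ncol = 2)
  sweep(pts %*% t(A$linear), 2, -A$translation)
}

#' Invert an affine transform
#' @param A `affine2d`.
#' @export
invert_affine <- function(A) {
  Li <- solve(A$linear)
  affine2d(Li, -as.vector(Li %*% A$translation))
}

#' Compose two affines: result applies `B` first, then `A`
#' @param A,B `affine2d` objects.
#' @export
compose_affine <- function(A, B) {
  affine2d(A$linear %*% B$linear,
           as.vector(A$linear %*% B$translation) + A$translation)
}

rot2 <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, -s, c), 2, 2)
}

#' Fit a constrained affine transform to point correspondences
#'
#' Least-squares optimal fit of `dst ~ linear %*% src + translation` within a
#' constraint class:
#' * `"full"`: unconstrained affine (>= 3 non-collinear points);
#' * `"rigid"`: rotation + translation (Kabsch-Umeyama);
#' * `"rigid+scale"`: rotation + single isotropic scale (Umeyama);
#' * `"noshear"`: rotation + independent x/y scales with exactly zero shear
#'   (the orthogonal but non-orthonormal Procrustes problem). Solved in
#'   closed form: after centering, the optimal rotation direction is the
#'   leading eigenvector of a 2x2 quadratic form, and the per-axis scales
#'   follow linearly.
#'
#' The translation is the difference between the destination mean and the
#' transformed source mean.
#'
#' @param src,dst N x 2 matrices.
#' @param constraint one of `"full"`, `"rigid"`, `"rigid+scale"`, `"noshear"`.
#' @param weights optional non-negative per-point weights.
#' @return `affine2d`.
#' @export
fit_affine <- function(src, dst, constraint = c("full", "rigid", "rigid+scale", "noshear"),
                       weights = NULL) {
  constraint <- match.arg(constraint)
  src <- matrix(src, ncol = 2); dst <- matrix(dst, ncol = 2)
  n <- nrow(src)
  stopifnot(nrow(dst) == n)
  minpts <- if (constraint == "full") 3L else 2L
  if (n < minpts) stop("need >= ", minpts, " correspondences for ", constraint, " fit")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  ms <- colSums(src * w); md <- colSums(dst * w)
  X <- sweep(src, 2, ms); Y <- sweep(dst, 2, md)
  Xw <- X * w
  L <- switch(constraint,
    full = {
      C <- crossprod(Xw, X)
      if (abs(det(C)) < 1e-12 * max(1, sum(X^2))^2)
        stop("degenerate geometry: source points are collinear")
      t(solve(C, crossprod(Xw, Y)))
    },
    rigid = {
      H <- crossprod(Xw, Y)        # sum w x y^T
      theta <- atan2(H[1, 2] - H[2, 1], H[1, 1] + H[2, 2])
      rot2(theta)
    },
    `rigid+scale` = {
      H <- crossprod(Xw, Y)
      theta <- atan2(H[1, 2] - H[2, 1], H[1, 1] + H[2, 2])
      num <- sqrt((H[1, 2] - H[2, 1])^2 + (H[1, 1] + H[2, 2])^2)
      s <- num / sum(w * rowSums(X^2))
      s * rot2(theta)
    },
    noshear = {
      U <- sum(w * X[, 1]^2); V <- sum(w * X[, 2]^2)
      if (U < 1e-300 || V < 1e-300)
        stop("degenerate geometry: no spread along one source axis")
      A1 <- sum(w * X[, 1] * Y[, 1]); B1 <- sum(w * X[, 1] * Y[, 2])
      A2 <- sum(w * X[, 2] * Y[, 2]); B2 <- sum(w * X[, 2] * Y[, 1])
      a <- c(A1, B1); b <- c(A2, -B2)
      Q <- tcrossprod(a) / U + tcrossprod(b) / V
      ev <- eigen(Q, symmetric = TRUE)
      cs <- ev$vectors[, 1]
      sx <- sum(cs * a) / U; sy <- sum(cs * b) / V
      if (sx + sy < 0) { cs <- -cs; sx <- -sx; sy <- -sy }
      rot2(atan2(cs[2], cs[1])) %*% diag(c(sx, sy))
    })
  affine2d(L, md - as.vector(L %*% ms))
}

#' Decompose an affine into angle, scales, shear and translation
#'
#' The linear part is factored as
#' `linear = R(angle) %*% diag(scale_x, scale_y) %*% [[1, shear_x], [shear_y, 1]]`
#' (rotation, then scale, then shear) via a sign-fixed QR factorization,
#' which makes the decomposition unique with `shear_y = 0`. No-shear fits
#' decompose with `shear_x` exactly zero (to machine epsilon); transforms
#' with a reflection surface as a negative `scale_y`.
#'
#' @param A `affine2d` with non-singular linear part.
#' @return list of class `affine_decomp`: `angle_deg`, `scale_x`, `scale_y`,
#'   `shear_x`, `shear_y`, `translation`.
#' @export
decompose_affine <- function(A) {
  L <- A$linear
  if (abs(det(L)) < 1e-300) stop("singular linear part cannot be decomposed")
  qrd <- qr(L)
  Q <- qr.Q(qrd); R <- qr.R(qrd)
  d <- sign(diag(R)); d[d == 0] <- 1
  Q <- Q %*% diag(d); R <- diag(d) %*% R
  if (det(Q) < 0) {            # reflection: push it into a negative y scale
    Q <- Q %*% diag(c(1, -1))
    R <- diag(c(1, -1)) %*% R
  }
  structure(list(angle_deg = atan2(Q[2, 1], Q[1, 1]) * 180 / pi,
                 scale_x = R[1, 1], scale_y = R[2, 2],
                 shear_x = R[1, 2] / R[1, 1], shear_y = 0,
                 translation = A$translation),
            class = "affine_decomp")
}

#' Recompose an affine from its decomposition
#' @param d `affine_decomp` (or compatible named list).
#' @return `affine2d`.
#' @export
compose_decomposition <- function(d) {
  sh <- matrix(c(1, d$shear_y, d$shear_x, 1), 2, 2)
  L <- rot2(d$angle_deg * pi / 180) %*% diag(c(d$scale_x, d$scale_y)) %*% sh
  affine2d(L, d$translation)
}

#' Per-point Euclidean residuals of an affine fit
#' @param A `affine2d`. @param src,dst N x 2 correspondence matrices.
#' @return numeric vector of residual norms.
#' @export
fit_residuals <- function(A, src, dst) {
  sqrt(rowSums((apply_affine(A, src) - dst)^2))
}

#' Seeded RANSAC fit of a constrained affine
#'
#' Repeatedly fits the model to minimal samples, scores inliers by residual
#' tolerance, then refits on the consensus set until the inlier set is
#' stable. The pair is flagged as a bad match when the final inlier count
#' falls below `min_inliers` or the fitted translation norm exceeds
#' `max_translation_nm`.
#'
#' @param src,dst N x 2 correspondence matrices (nm).
#' @param constraint as in [fit_affine()].
#' @param tolerance_nm inlier residual tolerance.
#' @param min_inliers minimum consensus size for a good match.
#' @param max_translation_nm translation heuristic threshold.
#' @param iters number of RANSAC iterations.
#' @param seed integer seed for deterministic sampling.
#' @return list: `ok`, `transform` (`affine2d` or NULL), `inliers` (logical),
#'   `n_inliers`, `reason` (for bad matches).
#' @export
ransac_fit <- function(src, dst, constraint = "rigid", tolerance_nm,
                       min_inliers = 1L, max_translation_nm = Inf,
                       iters = 1000L, seed = 1L) {
  stopifnot(tolerance_nm > 0)
  src <- matrix(src, ncol = 2); dst <- matrix(dst, ncol = 2)
  n <- nrow(src)
  bad <- function(reason) list(ok = FALSE, transform = NULL,
                               inliers = logical(n), n_inliers = 0L,
                               reason = reason)
  if (n == 0) return(bad("no correspondences"))
  k <- if (constraint == "full") 3L else 2L
  if (n < k) return(bad("too few correspondences"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  best_mask <- NULL; best_n <- -1L; best_err <- Inf
  for (it in seq_len(iters)) {
    idx <- sample.int(n, k)
    A <- tryCatch(fit_affine(src[idx, , drop = FALSE], dst[idx, , drop = FALSE],
                             constraint), error = function(e) NULL)
    if (is.null(A)) next
    r <- fit_residuals(A, src, dst)
    mask <- r <= tolerance_nm
    nin <- sum(mask)
    err <- sum(r[mask])
    if (nin > best_n || (nin == best_n && err < best_err)) {
      best_n <- nin; best_mask <- mask; best_err <- err
    }
  }
  if (is.null(best_mask) || best_n < k) return(bad("no consensus found"))
  mask <- best_mask
  A <- NULL
  for (rep in 1:10) {                 # refit until the inlier set is stable
    A <- tryCatch(fit_affine(src[mask, , drop = FALSE], dst[mask, , drop = FALSE],
                             constraint), error = function(e) NULL)
    if (is.null(A)) return(bad("degenerate consensus set"))
    new_mask <- fit_residuals(A, src, dst) <= tolerance_nm
    if (all(new_mask == mask)) break
    mask <- new_mask
    if (sum(mask) < k) return(bad("consensus collapsed"))
  }
  nin <- sum(mask)
  if (nin < min_inliers) return(bad(sprintf("only %d inliers (< %d)", nin, min_inliers)))
  if (sqrt(sum(A$translation^2)) > max_translation_nm)
    return(bad("translation exceeds maximum"))
  list(ok = TRUE, transform = A, inliers = mask, n_inliers = nin, reason = NULL)
}

#' Rigid moving-least-squares deformation / interpolation
#'
#' For every query point, fits the weighted rigid transform (weights
#' `1 / d^(2*alpha)` to the control sources) and applies it to the query.
#' This interpolates the controls exactly, reproduces any global rigid
#' transform at all queries, and extrapolates gracefully outside the control
#' hull.
#'
#' @param control_src,control_dst K x 2 control point matrices.
#' @param query M x 2 query points.
#' @param alpha weight falloff exponent (default 2).
#' @return M x 2 matrix of displaced query points.
#' @export
mls_rigid <- function(control_src, control_dst, query, alpha = 2) {
  p <- matrix(control_src, ncol = 2); q <- matrix(control_dst, ncol = 2)
  v <- matrix(query, ncol = 2)
  K <- nrow(p)
  if (K < 2) stop("need >= 2 control points")
  if (max(stats::dist(p)) < 1e-12) stop("control points must not all coincide")
  M <- nrow(v)
  out <- matrix(NA_real_, M, 2)
  d2 <- outer(rowSums(v^2), rep(1, K)) + outer(rep(1, M), rowSums(p^2)) -
    2 * v %*% t(p)
  d2[d2 < 0] <- 0
  hit <- d2 < 1e-18                       # coincident: take the control value
  W <- 1 / (d2^alpha + 1e-300)
  W[hit] <- 0
  any_hit <- rowSums(hit) > 0
  Ws <- rowSums(W)
  Wn <- W / Ws
  ps <- Wn %*% p; qs <- Wn %*% q          # weighted centroids per query
  # weighted rigid fit per query: theta = atan2(sum w (px qy - py qx)_hat, ...)
  a <- Wn %*% (p[, 1] * q[, 1] + p[, 2] * q[, 2]) -
    (ps[, 1] * qs[, 1] + ps[, 2] * qs[, 2])
  b <- Wn %*% (p[, 1] * q[, 2] - p[, 2] * q[, 1]) -
    (ps[, 1] * qs[, 2] - ps[, 2] * qs[, 1])
  theta <- atan2(b, a)
  cth <- cos(theta); sth <- sin(theta)
  dx <- v[, 1] - ps[, 1]; dy <- v[, 2] - ps[, 2]
  out[, 1] <- qs[, 1] + cth * dx - sth * dy
  out[, 2] <- qs[, 2] + sth * dx + cth * dy
  if (any(any_hit)) {
    ih <- which(any_hit)
    out[ih, ] <- q[apply(hit[ih, , drop = FALSE], 1, which.max), , drop = FALSE]
  }
  out
}
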