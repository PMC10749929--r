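# constrained affine fits, decomposition, RANSAC, rigid MLS

test_that("rigid fit recovers a planted rotation+translation exactly", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  R <- rigid_mat(30)
  dst <- sweep(sq %*% t(R), 2, -c(5, -2))
  d <- decompose_affine(fit_affine(sq, dst, "rigid"))
  expect_equal(d$angle_deg, 30, tolerance = 1e-9)
  expect_equal(c(d$scale_x, d$scale_y), c(1, 1), tolerance = 1e-9)
  expect_equal(d$shear_x, 0, tolerance = 1e-12)
})

test_that("noshear fit recovers anisotropic scale + rotation with zero residual", {
  set.seed(1)
  src <- matrix(runif(24, -4, 4), ncol = 2)
  L <- rigid_mat(10) %*% diag(c(1.1, 0.9))
  dst <- sweep(src %*% t(L), 2, -c(2, -1))
  fn <- fit_affine(src, dst, "noshear")
  expect_lt(max(abs(apply_affine(fn, src) - dst)), 1e-9)
  dn <- decompose_affine(fn)
  expect_equal(dn$angle_deg, 10, tolerance = 1e-7)
  expect_equal(c(dn$scale_x, dn$scale_y), c(1.1, 0.9), tolerance = 1e-9)
  # full affine recovers the same transform
  ff <- fit_affine(src, dst, "full")
  expect_equal(ff$linear, fn$linear, tolerance = 1e-9)
})

test_that("noshear fit of sheared data has exactly zero shear and larger residual than full", {
  set.seed(2)
  src <- matrix(runif(30, -3, 3), ncol = 2)
  dst <- src %*% t(matrix(c(1, 0, 0.2, 1), 2, 2))
  f_ns <- fit_affine(src, dst, "noshear")
  f_f <- fit_affine(src, dst, "full")
  expect_equal(decompose_affine(f_ns)$shear_x, 0, tolerance = 1e-13)
  expect_equal(decompose_affine(f_f)$shear_x, 0.2, tolerance = 1e-9)
  expect_gt(sum(fit_residuals(f_ns, src, dst)^2),
            sum(fit_residuals(f_f, src, dst)^2))
})

test_that("noshear closed form agrees with a numerical constrained optimizer", {
  set.seed(11)
  for (rep in 1:5) {
    src <- matrix(runif(20, -3, 3), ncol = 2)
    dst <- matrix(runif(20, -3, 3), ncol = 2)
    fn <- fit_affine(src, dst, "noshear")
    obj <- function(p) {
      A <- affine2d(rigid_mat(p[1]) %*% diag(p[2:3]), p[4:5])
      sum(fit_residuals(A, src, dst)^2)
    }
    d <- decompose_affine(fn)
    p0 <- c(d$angle_deg, d$scale_x, d$scale_y, fn$translation)
    opt <- optim(p0 + runif(5, -0.05, 0.05), obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    expect_lte(obj(p0), opt$value + 1e-7 * max(1, opt$value))
  }
})

test_that("residuals are ordered by constraint strength", {
  set.seed(4)
  src <- matrix(runif(28, -3, 3), ncol = 2)
  dst <- matrix(runif(28, -3, 3), ncol = 2)
  rss <- sapply(c("full", "noshear", "rigid+scale", "rigid"), function(cn)
    sum(fit_residuals(fit_affine(src, dst, cn), src, dst)^2))
  expect_true(all(diff(rss) >= -1e-9))
})

test_that("decompose/compose round-trips 1000 random invertible matrices", {
  set.seed(5)
  worst <- 0
  for (i in 1:1000) {
    M <- matrix(rnorm(4), 2, 2)
    if (abs(det(M)) < 1e-3) next
    A <- affine2d(M, rnorm(2))
    M2 <- compose_decomposition(decompose_affine(A))$linear
    worst <- max(worst, max(abs(M2 - M)))
  }
  expect_lt(worst, 1e-9)
})

test_that("identity and pure shear decompose as expected", {
  di <- decompose_affine(affine2d())
  expect_equal(c(di$angle_deg, di$scale_x, di$scale_y, di$shear_x),
               c(0, 1, 1, 0), tolerance = 1e-12)
  ds <- decompose_affine(affine2d(matrix(c(1, 0, 0.2, 1), 2, 2)))
  expect_equal(c(ds$angle_deg, ds$scale_x, ds$scale_y, ds$shear_x),
               c(0, 1, 1, 0.2), tolerance = 1e-12)
  expect_error(decompose_affine(affine2d(matrix(0, 2, 2))), "singular")
})

test_that("RANSAC excludes planted outliers and recovers the transform", {
  set.seed(6)
  pts <- matrix(runif(200, -50, 50), 100, 2)
  R <- rigid_mat(25)
  dst <- sweep(pts %*% t(R), 2, -c(1, 2))
  out_idx <- 1:20
  dst[out_idx, ] <- dst[out_idx, ] + matrix(runif(40, 30, 60), 20, 2)
  r <- ransac_fit(pts, dst, "rigid", tolerance_nm = 1, seed = 7)
  expect_true(r$ok)
  expect_true(all(!r$inliers[out_idx]))
  expect_true(all(r$inliers[-out_idx]))
  expect_lt(max(abs(r$transform$linear - R)), 1e-6)
})

test_that("RANSAC flags bad matches on count and translation heuristics", {
  set.seed(8)
  pts <- matrix(runif(20, -5, 5), 10, 2)
  dst <- pts + 1
  r <- ransac_fit(pts, dst, "rigid", tolerance_nm = 1, min_inliers = 32, seed = 1)
  expect_false(r$ok)
  r2 <- ransac_fit(pts, dst + 500, "rigid", tolerance_nm = 1,
                   max_translation_nm = 100, seed = 1)
  expect_false(r2$ok)
  # perfect correspondences: all inliers, zero residual, same as direct fit
  r3 <- ransac_fit(pts, dst, "rigid", tolerance_nm = 1, seed = 1)
  expect_true(all(r3$inliers))
  direct <- fit_affine(pts, dst, "rigid")
  expect_equal(r3$transform$linear, direct$linear, tolerance = 1e-9)
  expect_equal(r3$transform$translation, direct$translation, tolerance = 1e-9)
})

test_that("rigid MLS reproduces global rigid motion and interpolates controls", {
  set.seed(9)
  ctrl <- matrix(runif(10, -5, 5), 5, 2)
  R <- rigid_mat(23)
  cd <- sweep(ctrl %*% t(R), 2, -c(3, -2))
  q <- matrix(runif(100, -30, 30), 50, 2)   # includes points far outside hull
  expect_lt(max(abs(mls_rigid(ctrl, cd, q) - sweep(q %*% t(R), 2, -c(3, -2)))),
            1e-6)
  expect_equal(mls_rigid(ctrl, cd, ctrl), cd, tolerance = 1e-12)
})

test_that("MLS follows the local cluster motion (second-implementation oracle)", {
  set.seed(10)
  c1 <- matrix(runif(10, -10, -6), 5, 2)
  c2 <- matrix(runif(10, 6, 10), 5, 2)
  d1 <- sweep(c1, 2, -c(2, 0)); d2 <- sweep(c2, 2, -c(0, 3))
  q <- rbind(c1 + 0.2, c2 + 0.2)
  got <- mls_rigid(rbind(c1, c2), rbind(d1, d2), q)
  # independent direct implementation of the per-query weighted rigid fit
  oracle <- t(apply(q, 1, function(v) {
    p <- rbind(c1, c2); qq <- rbind(d1, d2)
    w <- 1 / (rowSums(sweep(p, 2, v)^2)^2)
    w <- w / sum(w)
    ps <- colSums(p * w); qs <- colSums(qq * w)
    ph <- sweep(p, 2, ps); qh <- sweep(qq, 2, qs)
    a <- sum(w * (ph[, 1] * qh[, 1] + ph[, 2] * qh[, 2]))
    b <- sum(w * (ph[, 1] * qh[, 2] - ph[, 2] * qh[, 1]))
    th <- atan2(b, a)
    Rv <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    as.vector(Rv %*% (v - ps)) + qs
  }))
  expect_equal(got, oracle, tolerance = 1e-9)
  expect_lt(max(abs(got[1:5, ] - (c1 + 0.2) - rep(c(2, 0), each = 5))), 0.01)
  expect_lt(max(abs(got[6:10, ] - (c2 + 0.2) - rep(c(0, 3), each = 5))), 0.01)
})
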