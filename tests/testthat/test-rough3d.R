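# coarse alignment, feature matching, pairwise affines, grid fields,
# blockwise rough solve and the no-shear refit

test_that("coarse alignment undoes a known ROI rotation", {
  ref <- fixture_phantom(160, 160, seed = 3)
  rot <- rotate_image(ref, 23, fill = 0)
  co <- coarse_align(rot, list(center_nm = c(79.5, 79.5) * 16, angle_deg = 23),
                     c(160, 160), 16)
  ctr <- 41:120
  expect_gt(stats::cor(as.vector(co$image[ctr, ctr]), as.vector(ref[ctr, ctr])),
            0.98)
  # zero-angle centered ROI is the identity crop
  co0 <- coarse_align(ref, list(center_nm = c(79.5, 79.5) * 16, angle_deg = 0),
                      c(160, 160), 16)
  expect_lt(max(abs(co0$image - ref)), 1e-9)
  expect_error(coarse_align(ref, list(center_nm = c(-50, 0), angle_deg = 0)),
               "outside")
})

test_that("the Lowe ratio test keeps and rejects as specified", {
  # descriptor geometry engineered so nearest/second-nearest distances are
  # exactly (1, 1.5) for keypoint 1 and (1, 1.3) for keypoint 2
  fA <- list(keypoints = rbind(c(0, 0), c(10, 10)),
             descriptors = rbind(c(0, 0, 0), c(5, 0, 0)))
  fB <- list(keypoints = rbind(c(1, 1), c(2, 2), c(3, 3), c(4, 4)),
             descriptors = rbind(c(1, 0, 0), c(0, 1.5, 0), c(5, 1, 0), c(5, 1.3, 0)))
  m <- match_sections(fA, fB, lowe_ratio = 1.42)
  # keypoint 1: d1 = 1 (desc 1), d2 = 1.5 (desc 2) -> ratio 1.5 >= 1.42 kept
  # keypoint 2: d1 = 1 (desc 3), d2 = 1.3 (desc 4) -> rejected
  expect_equal(nrow(m$src), 1)
  expect_equal(m$src[1, ], c(0, 0))
  expect_equal(m$dst[1, ], c(1, 1))
})

test_that("self-matching a section yields many near-zero displacements", {
  img <- fixture_phantom(220, 220, seed = 4)
  f <- detect_features(img, pixel_size_nm = 16)
  expect_gt(nrow(f$keypoints), 100)
  m <- match_sections(f, f, 1.42)
  expect_gt(nrow(m$src), 0.8 * nrow(f$keypoints))
  expect_lt(max(abs(m$src - m$dst)), 1e-9)
})

test_that("pairwise affines recover a known rigid transform between sections", {
  fx <- stack_fixture(n_sections = 2, shape_px = c(280, 280), pixel_size_nm = 512,
                      kind = "rigid", max_rot_deg = 4, max_trans_px = 12, seed = 6)
  feats <- lapply(fx$sections, detect_features, pixel_size_nm = 512)
  pairs <- neighbor_affines(feats, n_max = 1, pipeline_config(), seed = 2)
  expect_true(pairs[[1]]$ok)
  # compare against the exact planted pair transform at probe points
  pts <- cbind(runif(8, 70, 210), runif(8, 70, 210))
  tru <- {
    si <- pts + fx$truth$t_field(1, pts[, 1], pts[, 2])
    a <- si
    for (k in 1:25) a <- si - fx$truth$t_field(2, a[, 1], a[, 2])
    a
  }
  est <- apply_affine(pairs[[1]]$transform, pts * 512) / 512
  expect_lt(max(abs(est - tru)), 1)
})

test_that("affine fields behave analytically for identity, translation, rotation", {
  cfg <- pipeline_config(rough_grid_nm = 4000)
  mk_pair <- function(A) list(list(i = 1, j = 2, ok = TRUE, transform = A,
                                   n_inliers = 100, inlier_src = NULL))
  f_id <- affines_to_fields(mk_pair(affine2d()), c(40000, 30000), cfg)
  expect_lt(max(abs(f_id$comparisons[[1]]$delta)), 1e-9)
  f_tr <- affines_to_fields(mk_pair(affine2d(diag(2), c(700, -300))),
                            c(40000, 30000), cfg)
  expect_equal(f_tr$comparisons[[1]]$delta,
               matrix(rep(c(700, -300), each = nrow(f_tr$grid)), ncol = 2),
               tolerance = 1e-9)
  # rotation about the bbox center: |delta| grows linearly with radius
  ctr <- c(20000, 15000)
  th <- 2 * pi / 180
  A <- affine2d(rot2_test <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2),
                ctr - as.vector(rot2_test %*% ctr))
  f_rot <- affines_to_fields(mk_pair(A), c(40000, 30000), cfg)
  r <- sqrt(rowSums(sweep(f_rot$grid, 2, ctr)^2))
  mag <- sqrt(rowSums(f_rot$comparisons[[1]]$delta^2))
  expect_equal(mag, 2 * sin(th / 2) * r, tolerance = 1e-6)
})

test_that("the blockwise rough solve matches a dense per-grid-point oracle", {
  set.seed(7)
  n_sec <- 12
  grid <- hex_grid_points(8000, 6000, 3000)
  comps <- list()
  for (i in 1:(n_sec - 1)) for (n in 1:2) {
    j <- i + n
    if (j > n_sec) next
    comps[[length(comps) + 1]] <- list(
      i = i, j = j, delta = matrix(rnorm(2 * nrow(grid), sd = 50), ncol = 2),
      valid = rep(TRUE, nrow(grid)))
  }
  fields <- list(grid = grid, comparisons = comps)
  res <- rough_delta_solve(fields, n_sec, pipeline_config())
  # oracle: dense solve + linear trend removal, per grid point
  for (gpt in c(1, nrow(grid) %/% 2)) {
    src <- sapply(comps, `[[`, "i"); dst <- sapply(comps, `[[`, "j")
    d <- t(sapply(comps, function(c) c$delta[gpt, ]))
    x <- dense_lss_oracle(n_sec, src, dst, d)
    x <- x - cbind(1, 1:n_sec) %*% qr.coef(qr(cbind(1, 1:n_sec)), x)
    expect_equal(res$u[, gpt, ], unname(x), tolerance = 1e-8)
  }
})

test_that("a single translated section is pulled back while others stay put", {
  n_sec <- 8
  grid <- hex_grid_points(5000, 4000, 2000)
  ng <- nrow(grid)
  t_of <- function(i) if (i == 4) c(400, 0) else c(0, 0)
  comps <- list()
  for (i in 1:(n_sec - 1)) for (n in 1:2) {
    j <- i + n
    if (j > n_sec) next
    d <- matrix(rep(t_of(i) - t_of(j), each = ng), ncol = 2)
    comps[[length(comps) + 1]] <- list(i = i, j = j, delta = d,
                                       valid = rep(TRUE, ng))
  }
  res <- rough_delta_solve(list(grid = grid, comparisons = comps), n_sec,
                           pipeline_config())
  # the aligning lookup displacement for section 4 is -t (sampling at
  # q + u undoes the planted content offset t); relative to the others it
  # must recover the planted 400 nm with opposite sign
  rel <- res$u[4, 1, 1] - mean(res$u[-4, 1, 1])
  expect_equal(rel, -400, tolerance = 1)
  expect_lt(max(abs(res$u[, 1, 2])), 1e-6)
})

test_that("no-shear refit reproduces the shear pathology contrast", {
  grid <- hex_grid_points(8000, 8000, 1500)
  # field generated from a sheared affine
  sh <- affine2d(matrix(c(1, 0, 0.15, 1), 2, 2), c(0, 0))
  u <- apply_affine(sh, grid) - grid
  full <- refit_section_affine(grid, u, constraint = "full")
  ns <- refit_section_affine(grid, u, constraint = "noshear")
  expect_gt(abs(decompose_affine(full)$shear_x), 0.1)
  expect_equal(decompose_affine(ns)$shear_x, 0, tolerance = 1e-12)
  expect_gt(sum((apply_affine(ns, grid) - grid - u)^2),
            sum((apply_affine(full, grid) - grid - u)^2))
  # a no-shear generating transform is recovered exactly
  gen <- affine2d(rigid_mat(1.7) %*% diag(c(1.05, 0.97)), c(120, -60))
  u2 <- apply_affine(gen, grid) - grid
  rec <- refit_section_affine(grid, u2, constraint = "noshear")
  expect_equal(rec$linear, gen$linear, tolerance = 1e-9)
  expect_warning(refit_section_affine(grid, u2, valid = rep(FALSE, nrow(grid))),
                 "identity")
})
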