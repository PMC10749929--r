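# elastic fine alignment: masked grids, deltas, outlier handling, MLS
# replacement, affine filter and the per-grid-point delta solve

test_that("masked hexagonal grids honor ROI and have 6 equidistant neighbors", {
  g_all <- make_masked_grid(c(200, 240), 16, 480)
  expect_true(all(g_all$active))
  # interior points have exactly 6 neighbors at the lattice spacing
  d <- as.matrix(dist(g_all$grid))
  interior <- which(g_all$grid[, 1] > 700 & g_all$grid[, 1] < 3000 &
                      g_all$grid[, 2] > 700 & g_all$grid[, 2] < 2400)
  for (i in interior[1:4]) {
    nb <- unname(sort(d[i, d[i, ] > 1])[1:6])
    expect_equal(nb, rep(480, 6), tolerance = 1e-6)
  }
  # left-half ROI deactivates the right half
  roi <- list(center_nm = c(800, 1590), angle_deg = 0, halfsize_nm = c(800, 1600))
  g_roi <- make_masked_grid(c(200, 240), 16, 480, roi = roi)
  right <- g_roi$grid[, 1] > 800 * 1.1 + 800 + 1
  expect_true(all(!g_roi$active[right]))
})

test_that("identical and translated neighbors measure the expected deltas", {
  ph <- fixture_phantom(280, 280, seed = 2)
  shift <- c(6, -4)
  ph2 <- matrix(bilinear_sample(ph, coord_grid(280, 280)$x - shift[1],
                                coord_grid(280, 280)$y - shift[2], fill = 0),
                280, 280)    # content moved by +shift
  cfg <- pipeline_config(fine_grid_nm = 40 * 16, fine_src_crop_nm = 96 * 16,
                         fine_dst_crop_nm = 24 * 16, fine_n_neighbors = 1,
                         rot_sweep_deg = 0)
  params <- fine_params(cfg, "fine")
  grid <- make_masked_grid(c(280, 280), 16, params$grid_nm, config = cfg)
  f_same <- measure_fine_deltas(list(ph, ph), grid, params, 16, cfg)
  cmp <- f_same$comparisons[[1]]
  expect_true(all(abs(cmp$delta[cmp$valid, ]) <= 1e-9))
  expect_true(all(cmp$peak[cmp$valid] > 0.98))
  # planted shift: section 2 content at a equals section 1 at a - shift,
  # i.e. t_2 = -shift relative to t_1 = 0; delta = t_1 - t_2 = +shift (nm)
  f_sh <- measure_fine_deltas(list(ph, ph2), grid, params, 16, cfg)
  cs <- f_sh$comparisons[[1]]
  meas <- cs$delta[cs$valid, ] / 16
  expect_true(all(abs(sweep(meas, 2, shift)) <= 1))
})

test_that("quadratic RANSAC flags planted gross outliers and keeps a clean field", {
  set.seed(3)
  grid <- hex_grid_points(40000, 32000, 2500)
  ng <- nrow(grid)
  x <- grid[, 1] / 40000; y <- grid[, 2] / 32000
  delta <- cbind(3000 * x^2 - 1000 * y + 500 * x * y,
                 -2000 * y^2 + 800 * x)
  active <- rep(TRUE, ng)
  # reconsideration diameter scaled to ~3.6 grid spacings as in production
  cfg <- pipeline_config(reconsider_diam_nm = 9000)
  clean <- detect_outliers(delta, grid, active, active, cfg, seed = 4)
  expect_equal(clean$inlier_fraction, 1)
  out_idx <- sample(ng, round(0.1 * ng))
  spiked <- delta
  spiked[out_idx, ] <- spiked[out_idx, ] +
    matrix(runif(2 * length(out_idx), 30000, 60000) *
             sample(c(-1, 1), 2 * length(out_idx), TRUE), ncol = 2)
  det <- detect_outliers(spiked, grid, active, active, cfg, seed = 4)
  expect_true(all(!det$inlier[out_idx]))
  expect_true(all(det$inlier[-out_idx]))
})

test_that("a borderline rejected delta consistent with its neighbors is re-admitted", {
  grid <- hex_grid_points(40000, 32000, 2500)
  ng <- nrow(grid)
  delta <- cbind(rep(1000, ng), rep(0, ng))
  # one point carries a delta outside the quadratic-RANSAC band but aligned
  # with its local neighborhood after we also perturb that neighborhood
  ctr <- which.min(rowSums(sweep(grid, 2, c(20000, 16000))^2))
  nbh <- which(sqrt(rowSums(sweep(grid, 2, grid[ctr, ])^2)) < 8000)
  # a coherent locally warped patch: far outside the RANSAC band relative
  # to the global model, but mutually consistent in angle and magnitude,
  # so its members are re-admitted by the neighborhood comparison
  delta[nbh, 1] <- delta[nbh, 1] + 30000
  cfg <- pipeline_config(reconsider_diam_nm = 9000)
  det <- detect_outliers(delta, grid, rep(TRUE, ng), rep(TRUE, ng), cfg, seed = 5)
  expect_true(any(det$readmitted[nbh]))
  # incoherent gross outliers stay rejected
  delta2 <- cbind(rep(1000, ng), rep(0, ng))
  lone <- c(ctr, ctr + 1L)
  delta2[lone, ] <- matrix(c(40000, -35000, -38000, 42000), 2, 2)
  det2 <- detect_outliers(delta2, grid, rep(TRUE, ng), rep(TRUE, ng), cfg, seed = 5)
  expect_true(all(!det2$inlier[lone]))
})

test_that("MLS replacement reproduces rigid motion and leaves inliers untouched", {
  grid <- hex_grid_points(30000, 24000, 3000)
  ng <- nrow(grid)
  R <- rigid_mat(2)
  delta <- sweep(grid %*% t(R), 2, -c(500, -300)) - grid
  inlier <- rep(TRUE, ng); inlier[c(3, 10, 17)] <- FALSE
  dmiss <- delta; dmiss[!inlier, ] <- NA
  rep_ <- replace_outliers(dmiss, grid, inlier, rep(TRUE, ng),
                           pipeline_config())
  expect_true(rep_$ok)
  expect_equal(rep_$delta[c(3, 10, 17), ], delta[c(3, 10, 17), ], tolerance = 1e-6)
  expect_equal(rep_$weight[c(3, 10, 17)], rep(0.5, 3))
  expect_true(all(rep_$weight[inlier] == 1))
  # no outliers: field unchanged
  rep0 <- replace_outliers(delta, grid, rep(TRUE, ng), rep(TRUE, ng),
                           pipeline_config())
  expect_equal(rep0$delta, delta)
})

test_that("the affine filter fixes affine fields and attenuates spikes", {
  grid <- hex_grid_points(40000, 32000, 2000)
  A <- affine2d(matrix(c(1.01, 0.003, -0.002, 0.99), 2, 2), c(300, -200))
  delta <- apply_affine(A, grid) - grid
  filt <- affine_filter(delta, grid, 8000)
  expect_lt(max(abs(filt - delta)), 1e-9)
  spiked <- delta
  k <- which.min(rowSums(sweep(grid, 2, c(20000, 16000))^2))  # interior point
  spiked[k, ] <- spiked[k, ] + c(5000, -4000)
  filt2 <- affine_filter(spiked, grid, 8000)
  expect_lt(sqrt(sum((filt2[k, ] - delta[k, ])^2)),
            sqrt(sum(c(5000, -4000)^2)) / 10)
  # attenuation grows with spatial frequency
  att <- sapply(c(30000, 8000), function(wl) {
    wave <- cbind(800 * sin(2 * pi * grid[, 1] / wl), 0)
    out <- affine_filter(wave, grid, 8000)
    sqrt(mean((out - wave)^2)) / sqrt(mean(wave^2))
  })
  expect_lt(att[1], att[2])
  expect_lt(att[1], 0.2)
})

test_that("the fine delta solve matches a dense weighted oracle and zero maps to zero", {
  set.seed(6)
  n_sec <- 9
  grid <- hex_grid_points(6000, 5000, 2500)
  ng <- nrow(grid)
  comps <- list()
  for (i in 1:(n_sec - 1)) for (n in 1:2) {
    j <- i + n
    if (j > n_sec) next
    comps[[length(comps) + 1]] <- list(
      i = i, j = j, delta = matrix(rnorm(2 * ng, sd = 40), ncol = 2),
      valid = rep(TRUE, ng),
      weight = sample(c(1, 0.5), ng, TRUE))
  }
  fields <- list(grid = grid, comparisons = comps)
  wfn <- function(n_off) c(1, 1, 0.4, 0.1)[min(n_off, 4)]
  res <- emstitch:::solve_grid_deltas(fields, n_sec, pipeline_config(),
                                      weights_fn = wfn, detrend = FALSE)
  gpt <- 2
  src <- sapply(comps, `[[`, "i"); dst <- sapply(comps, `[[`, "j")
  d <- t(sapply(comps, function(c) c$delta[gpt, ]))
  w <- sapply(comps, function(c) wfn(c$j - c$i) * c$weight[gpt])
  expect_equal(res$u[, gpt, ], unname(dense_lss_oracle(n_sec, src, dst, d, w)),
               tolerance = 1e-8)
  # all-zero fields solve to zero
  z <- lapply(comps, function(c) { c$delta[] <- 0; c })
  rz <- emstitch:::solve_grid_deltas(list(grid = grid, comparisons = z), n_sec,
                                     pipeline_config(), detrend = FALSE)
  expect_lt(max(abs(rz$u)), 1e-10)
})
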