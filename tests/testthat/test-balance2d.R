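# gradient/brightness corrections and the sub-tile histogram refinement

hex7 <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, -1), c(-1, 1))

test_that("identical tiles average to themselves with zero rejections", {
  fx <- montage_fixture(seed = 1, mfov_ab = hex7, jitter_sd_px = 0)
  # same content for every tile of one beam position
  for (k in seq_along(fx$tiles))
    fx$tiles[[k]]$image <- fx$tiles[[((k - 1) %% 7) + 1]]$image
  av <- average_beam_tiles(fx$tiles, pipeline_config())
  expect_equal(nrow(av$rejections), 0)
  for (b in 1:7)
    expect_equal(av$mean_tiles[[b]], fx$tiles[[b]]$image, tolerance = 1e-12)
  off <- brightness_pass(av$mean_tiles)
  expect_true(all(abs(off - mean(off)) <= max(abs(off)) + 1e-9))
})

test_that("tiles with large out-of-range components are rejected", {
  fx <- montage_fixture(seed = 2, mfov_ab = hex7, jitter_sd_px = 0)
  bad <- fx$tiles[[4]]$image
  # dark silicon-like region: 22% of the tile (over the 20% component rule)
  # but under 0.5% of the whole section, so the histogram range stays put
  bad[1:50, 1:63] <- 2
  fx$tiles[[4]]$image <- bad
  av <- average_beam_tiles(fx$tiles, pipeline_config())
  expect_true(4 %in% av$rejections$tile)
})

test_that("planted offsets on identical-content tiles are recovered within a gray level", {
  base <- fixture_phantom(112, 128, seed = 3)
  offs <- c(10, -10, 0, 6, -6, 3, -3)
  tiles <- list()
  for (m in 1:5) for (b in 1:7)
    tiles[[length(tiles) + 1]] <- list(image = clamp255(base + offs[b]),
                                       mfov_id = m, beam_id = b,
                                       nominal_xy = c(0, 0), pixel_size_nm = 16)
  av <- average_beam_tiles(tiles, pipeline_config())
  rec <- brightness_pass(av$mean_tiles)
  expect_true(all(abs(rec - offs) <= 1))
})

test_that("gradient pass flattens a planted multiplicative gradient", {
  ph <- fixture_phantom(480, 540, seed = 4)
  g <- coord_grid(112, 128)
  rr <- ((g$x - 60)^2 + (g$y - 50)^2); rr <- rr / max(rr)
  grad <- 1 - 0.2 * pmax(0, (rr - 0.2) / 0.8)
  # 16 tiles of one beam with different tissue content under one gradient
  offs <- expand.grid(r = c(1, 123, 245, 367), c = c(1, 134, 267, 400))
  crops <- lapply(seq_len(16), function(m)
    ph[offs$r[m] + 0:111, offs$c[m] + 0:127])
  tiles <- lapply(seq_len(16), function(m)
    list(image = clamp255(crops[[m]] * grad), mfov_id = m, beam_id = 1,
         nominal_xy = c(0, 0), pixel_size_nm = 16))
  cfg <- pipeline_config(gradient_box_nm = 512)
  av <- average_beam_tiles(tiles, cfg)
  sc <- gradient_pass(av$mean_tiles, 16, cfg)[[1]]
  # correcting a tile flattens the planted gradient within a few percent
  # away from borders (bright enough pixels only)
  corrected <- (crops[[1]] * grad) / sc
  sel <- crops[[1]][20:92, 20:108] > 60
  interior <- (corrected[20:92, 20:108] / crops[[1]][20:92, 20:108])[sel]
  expect_lt(stats::sd(interior), 0.05)
  # the scale raster itself is mode-normalized near 1
  expect_equal(which.max(tabulate(round(sc * 100))), 100, tolerance = 4)
})

test_that("histogram lags between brightness-shifted sub-tiles solve to centered offsets", {
  base <- fixture_phantom(40, 40, seed = 5)
  # two-node system: +7 gray shift -> lag 7 -> offsets -3.5 / +3.5
  H <- cbind(hist256(base) / 1600, hist256(clamp255(base + 7)) / 1600)
  tab <- emstitch:::hist_lag_table(H)
  expect_equal(tab$lag, 7)
  sol <- solve_deltas(delta_graph(2, tab$src, tab$dst, matrix(tab$lag, ncol = 1)))
  expect_equal(sol$coords[, 1], c(-3.5, 3.5), tolerance = 1e-9)
})

test_that("sub-tile refinement recovers a planted brightness field sampled at sub-tiles", {
  # every tile has distinct tissue content, as in a real section; the
  # brightness field is evaluated at sub-tile centers and planted as
  # per-sub-tile constants
  ph <- fixture_phantom(480, 540, seed = 6)
  offs <- expand.grid(r = c(1, 123, 245, 367), c = c(1, 134, 267, 400))
  ys <- round(seq(0, 112, length.out = 4)); xs <- round(seq(0, 128, length.out = 4))
  tiles <- list()
  planted <- matrix(0, 16, 9)
  for (k in 1:16) {
    amp <- 20 * sin(k); dir <- k
    img <- ph[offs$r[k] + 0:111, offs$c[k] + 0:127]
    i <- 0
    for (r in 1:3) for (c in 1:3) {
      i <- i + 1
      cx <- (xs[c] + xs[c + 1]) / 2 / 128 - 0.5
      cy <- (ys[r] + ys[r + 1]) / 2 / 112 - 0.5
      planted[k, i] <- round(amp * (cos(dir) * cx + sin(dir) * cy))
      img[(ys[r] + 1):ys[r + 1], (xs[c] + 1):xs[c + 1]] <-
        img[(ys[r] + 1):ys[r + 1], (xs[c] + 1):xs[c + 1]] + planted[k, i]
    }
    tiles[[k]] <- list(image = clamp255(img), mfov_id = k, beam_id = 1,
                       nominal_xy = c(0, 0), pixel_size_nm = 16)
  }
  ref <- subtile_histogram_refine(tiles, pipeline_config())
  planted <- planted - mean(planted)
  # lag comparisons between distinct-content sub-tiles carry a 1-2 gray
  # noise floor at this sub-tile count (production sections draw the top-32
  # neighbors from thousands of sub-tiles), so recovery of the field shape
  # is strong but not exact
  expect_gt(stats::cor(as.vector(ref$subtile_offsets), as.vector(planted)), 0.85)
  expect_lt(sqrt(mean((ref$subtile_offsets - planted)^2)), 2.5)
})

test_that("MST augmentation keeps disconnected intensity clusters in one system", {
  # two clusters of sub-tile histograms with no overlap in content
  set.seed(7)
  h1 <- replicate(6, hist256(clamp255(fixture_phantom(30, 30, seed = sample(1e6, 1)))) / 900)
  h2 <- replicate(6, hist256(clamp255(fixture_phantom(30, 30, seed = sample(1e6, 1)) * 0.3 + 180)) / 900)
  tiles <- lapply(1:4, function(k)
    list(image = if (k <= 2) fixture_phantom(36, 36, seed = k)
         else clamp255(fixture_phantom(36, 36, seed = k) * 0.3 + 180),
         mfov_id = 1, beam_id = k, nominal_xy = c(0, 0), pixel_size_nm = 16))
  ref <- subtile_histogram_refine(tiles, pipeline_config(hist_top_n = 2,
                                                         subtile_grid = c(2, 2)))
  # a single connected solve: all offsets finite and mean-centered
  expect_true(all(is.finite(ref$subtile_offsets)))
  expect_lt(abs(mean(ref$subtile_offsets)), 1e-6)
})

test_that("the full correction stack restores a corrupted fixture", {
  fx <- montage_fixture(seed = 14, mfov_ab = hexring(2), jitter_sd_px = 0,
                        gradient_range = c(0.8, 1.2), offset_amp = 10)
  cfg <- pipeline_config(gradient_box_nm = 512)
  corr <- beam_corrections(fx$tiles, cfg)
  errs <- sapply(seq_along(fx$tiles), function(i) {
    img <- apply_corrections(fx$tiles[[i]], corr, i)
    tl <- fx$truth$tl_px[i, ] - fx$phantom_origin_nm / 16
    clean <- fx$phantom[tl[2] + seq_len(112), tl[1] + seq_len(128)]
    mean(abs(img - clean))
  })
  raw <- sapply(seq_along(fx$tiles), function(i) {
    tl <- fx$truth$tl_px[i, ] - fx$phantom_origin_nm / 16
    clean <- fx$phantom[tl[2] + seq_len(112), tl[1] + seq_len(128)]
    mean(abs(fx$tiles[[i]]$image - clean))
  })
  expect_lt(mean(errs), mean(raw))         # corrections help
  expect_lt(mean(errs), 4)                 # close to the clean tiles
})
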