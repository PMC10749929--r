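# 2D montaging: neighbor graph, deltas, two-pass outliers, solve, render

test_that("hexagonal neighbor graph has the right degrees", {
  fx <- montage_fixture(seed = 1, mfov_ab = rbind(c(0, 0)), jitter_sd_px = 0)
  edges <- build_neighbor_graph(fx$tiles, fx$layout)
  deg <- tabulate(c(edges$src, edges$dst), 7)
  expect_equal(deg[1], 6)                  # center beam
  expect_true(all(deg[2:7] == 3))          # ring beams
  expect_true(all(edges$class == "intra"))
  # each unordered pair appears once
  expect_false(any(duplicated(paste(pmin(edges$src, edges$dst),
                                    pmax(edges$src, edges$dst)))))
})

test_that("inter edges connect only facing perimeter tiles of adjacent mFOVs", {
  fx <- montage_fixture(seed = 2, mfov_ab = rbind(c(0, 0), c(1, 0)),
                        jitter_sd_px = 0)
  edges <- build_neighbor_graph(fx$tiles, fx$layout)
  inter <- edges[edges$class == "inter", ]
  expect_gt(nrow(inter), 0)
  mf <- sapply(fx$tiles, function(t) t$mfov_id)
  expect_true(all(mf[inter$src] != mf[inter$dst]))
  # facing tiles only: nominal separation below one tile width
  tw <- fx$layout$tile_shape_px[2] * 16
  expect_true(all(sqrt(inter$nominal_dx^2 + inter$nominal_dy^2) < 1.05 * tw))
})

test_that("measured deltas reproduce the planted cut positions within a pixel", {
  fx <- montage_fixture(seed = 5, mfov_ab = rbind(c(0, 0)), jitter_sd_px = 0.5)
  edges <- build_neighbor_graph(fx$tiles, fx$layout)
  edges <- measure_deltas(fx$tiles, edges, pipeline_config())
  truth <- fx$truth$true_xy[edges$dst, ] - fx$truth$true_xy[edges$src, ]
  err_px <- abs(cbind(edges$dx, edges$dy) - truth) / 16
  expect_true(all(err_px <= 1 + 1e-9))
})

test_that("blank tiles are variance-flagged; planted jitter shifts deltas exactly", {
  fx <- montage_fixture(seed = 7, mfov_ab = rbind(c(0, 0)), jitter_sd_px = 0)
  fx$tiles[[3]]$image <- matrix(128, 112, 128)
  edges <- build_neighbor_graph(fx$tiles, fx$layout)
  edges <- measure_deltas(fx$tiles, edges, pipeline_config())
  touching <- edges$src == 3 | edges$dst == 3
  expect_true(all(edges$var_outlier[touching]))
  expect_true(all(!edges$var_outlier[!touching]))
})

test_that("two-pass outlier handling flags and median-replaces planted outliers", {
  fx <- montage_fixture(seed = 8, mfov_ab = rbind(c(0, 0), c(1, 0), c(0, 1)),
                        jitter_sd_px = 0)
  edges <- build_neighbor_graph(fx$tiles, fx$layout)
  edges <- measure_deltas(fx$tiles, edges, pipeline_config())
  clean <- outlier_two_pass(edges, pipeline_config())
  expect_equal(sum(clean$outlier), 0)
  expect_true(all(abs(clean$dx - edges$dx) < 1e-9))

  # gross intra outlier (+5 um) -> pass 1; 100 nm from median -> pass 2
  spike <- edges
  i1 <- which(spike$class == "intra")[1]
  spike$dx[i1] <- spike$dx[i1] + 5000
  i2 <- which(spike$class == "intra")[5]
  spike$dx[i2] <- spike$dx[i2] + 100
  out <- outlier_two_pass(spike, pipeline_config())
  expect_true(out$pass1[i1]); expect_true(out$replaced[i1])
  expect_false(out$pass1[i2]); expect_true(out$pass2[i2])
  expect_equal(out$weight[i1], 0.5)
  # replacement equals the direction median of surviving edges
  key_dir <- abs(spike$nominal_dx - spike$nominal_dx[i1]) < 10 &
    abs(spike$nominal_dy - spike$nominal_dy[i1]) < 10 & spike$class == "intra"
  med <- stats::median(edges$dx[key_dir & seq_along(key_dir) != i1])
  expect_equal(out$dx[i1], med, tolerance = 1)
})

test_that("section solve recovers true positions from jittered tiles", {
  fx <- montage_fixture(seed = 9, mfov_ab = rbind(c(0, 0), c(1, 0)),
                        jitter_sd_px = 0.5)
  res <- montage_section(fx$tiles, fx$layout, NULL, pipeline_config())
  truth <- sweep(fx$truth$true_xy, 2, colMeans(fx$truth$true_xy))
  rms_px <- sqrt(mean(rowSums((res$coords_nm - truth)^2))) / 16
  expect_lt(rms_px, 1)
  expect_lt(mean(res$residual_nm) / 16, 1)
})

test_that("feathered rendering is a partition of unity", {
  fx <- montage_fixture(seed = 10, mfov_ab = rbind(c(0, 0)), jitter_sd_px = 0)
  # single tile: montage equals the tile
  mon1 <- render_montage(fx$tiles[1], matrix(0, 1, 2), NULL, NULL,
                         pipeline_config())
  expect_equal(mon1$image, fx$tiles[[1]]$image, ignore_attr = TRUE)
  # two overlapping tiles with identical content in the overlap
  img <- fixture_phantom(112, 190, seed = 12)
  t1 <- list(image = img[, 1:128], mfov_id = 1, beam_id = 1,
             nominal_xy = c(0, 0), pixel_size_nm = 16)
  t2 <- list(image = img[, 63:190], mfov_id = 1, beam_id = 2,
             nominal_xy = c(62 * 16, 0), pixel_size_nm = 16)
  mon2 <- render_montage(list(t1, t2), rbind(c(0, 0), c(62 * 16, 0)),
                         NULL, NULL, pipeline_config())
  expect_equal(dim(mon2$image), c(112, 190))
  expect_lt(max(abs(mon2$image - img)), 1e-9)
})

test_that("rendering is invariant to tile processing order", {
  # a 1-mFOV fixture can legitimately lose a direction's only delta, which
  # triggers the documented nominal-fallback warning
  fx <- montage_fixture(seed = 13, mfov_ab = rbind(c(0, 0)), jitter_sd_px = 0.5)
  res <- suppressWarnings(
    montage_section(fx$tiles, fx$layout, NULL, pipeline_config()))
  perm <- c(4, 2, 7, 1, 5, 3, 6)
  mon_p <- render_montage(fx$tiles[perm], res$coords_nm[perm, ],
                          NULL, NULL, pipeline_config())
  expect_lt(max(abs(res$image - mon_p$image)), 1e-9)
  # the solved coordinates themselves agree across input orderings to
  # within the integer-pixel measurement resolution (a 1-mFOV fixture can
  # legitimately lose a direction's only delta, hence the warning guard)
  res_p <- suppressWarnings(
    montage_section(fx$tiles[perm], fx$layout, NULL, pipeline_config()))
  back <- res_p$coords_nm[order(perm), ]
  expect_lt(max(abs(back - res$coords_nm)) / 16, 1)
})
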