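test_that("rendered nucleus has the design extents and volume", {
  params <- sim_params()
  r <- render_nucleus(nucleus_spec(), params)
  vox <- arrayInd(which(r$mask), dim(r$mask))
  co <- voxel_coords(vox, params$spacing)

  # antero-posterior extent 12 um within one in-plane voxel (extents span
  # voxel boxes, so one voxel width is added to the centre-to-centre range)
  expect_lt(abs(max(co[, 1]) - min(co[, 1]) + 0.093 - 12), 0.093)
  # depth extent 3 um within one axial voxel
  expect_lt(abs(max(co[, 3]) - min(co[, 3]) + 0.244 - 3), 0.244)

  # voxel volume vs closed-form ellipsoid volume within 5%
  v_vox <- nrow(vox) * prod(params$spacing)
  v_true <- 4 / 3 * pi * 6 * 3.5 * 1.5
  expect_equal(v_vox, v_true, tolerance = 0.05)
})

test_that("nucleus voxel count is rotation invariant within 2%", {
  params <- sim_params()
  n0 <- sum(render_nucleus(nucleus_spec(theta = 0), params)$mask)
  n90 <- sum(render_nucleus(nucleus_spec(theta = pi / 2), params)$mask)
  n37 <- sum(render_nucleus(nucleus_spec(theta = 0.65), params)$mask)
  expect_equal(n90 / n0, 1, tolerance = 0.02)
  expect_equal(n37 / n0, 1, tolerance = 0.02)
})

test_that("a nucleus larger than the requested stack is rejected", {
  params <- sim_params()
  expect_error(render_nucleus(nucleus_spec(), params, dims = c(5, 40, 40)),
               "exceeds stack bounds")
  expect_error(nucleus_spec(semi_axes = c(2, 3, 1)), "ap >= lateral >= depth")
})

test_that("spot clusters merge within a cluster and stay separate across clusters", {
  params <- sim_params()
  nuc <- render_nucleus(nucleus_spec(), params)
  cfg <- seg_config()

  # one cluster of 4 members within the jitter radius -> one component
  set.seed(5)
  one <- data.frame(member_count = 4L, ap_percent = 50, ml_percent = 20,
                    azimuth = 0)
  sig <- render_spots(one, nuc, params)
  mask1 <- sig > cfg$manual_threshold
  expect_equal(max(oracle_flood_fill(mask1, 26)), 1)

  # 12 well-separated clusters -> segmentation recovers exactly 12
  set.seed(6)
  g <- expand.grid(ap = c(20, 35, 50, 65, 80, 92) - 2, ml = c(25, 65))
  many <- data.frame(member_count = rep(2L, 12), ap_percent = g$ap,
                     ml_percent = g$ml, azimuth = 0)
  sig12 <- render_spots(many, nuc, params)
  st <- image_stack(list(
    dna = spermfish3d:::.apply_noise(nuc$signal, params),
    telomere = spermfish3d:::.apply_noise(sig12, params)), params$spacing)
  nobj <- segment_nucleus(st, cfg)
  expect_equal(count_clusters(segment_signals(st, "telomere", nobj, cfg)), 12)

  # no clusters -> pure background noise after noise application
  empty <- render_spots(data.frame(), nuc, params)
  expect_true(all(empty == 0))

  # a cluster centre outside the nucleus is a hard error
  outside <- data.frame(member_count = 1L, ap_percent = 50, ml_percent = 115,
                        azimuth = 0)
  expect_error(render_spots(outside, nuc, params), "outside the nucleus")
})

test_that("territory blobs honour their design shape and volume", {
  params <- sim_params()
  nuc <- render_nucleus(nucleus_spec(), params)
  cfg <- seg_config()
  seg_ct <- function(spec) {
    sig <- render_ct(spec, nuc, params)
    st <- image_stack(list(dna = spermfish3d:::.apply_noise(nuc$signal, params),
                           ct = spermfish3d:::.apply_noise(sig, params)),
                      params$spacing)
    nobj <- segment_nucleus(st, cfg)
    segment_signals(st, "ct", nobj, cfg)[[1]]
  }
  axis_ratio <- function(obj) {
    co <- voxel_coords(obj$voxels, obj$spacing)
    l <- sqrt(eigen(cov(co), symmetric = TRUE, only.values = TRUE)$values)
    l[1] / l[2]
  }

  set.seed(21)
  # a sphere-designed blob segments to a near-unit axis ratio
  round_ct <- ct_spec("ssc17", 50, 30, shape = "round",
                      elongation_ratio = 1, volume_um3 = 3)
  expect_lte(axis_ratio(seg_ct(round_ct)), 1.15)

  # a 3:1 blob segments to a ratio within 10%
  long_ct <- ct_spec("ssc13", 50, 30, shape = "elongated",
                     elongation_ratio = 3, volume_um3 = 8)
  r <- axis_ratio(seg_ct(long_ct))
  expect_gte(r, 2.7); expect_lte(r, 3.3)

  # doubling the design volume doubles the segmented voxel count within 10%
  v1 <- seg_ct(ct_spec("ssc17", 45, 25, elongation_ratio = 1.2,
                       volume_um3 = 2.5))$n_voxels
  v2 <- seg_ct(ct_spec("ssc17", 45, 25, elongation_ratio = 1.2,
                       volume_um3 = 5))$n_voxels
  expect_equal(v2 / v1, 2, tolerance = 0.1)

  # a territory that cannot fit the nucleus is rejected
  expect_error(render_ct(ct_spec("ssc13", 50, 95, volume_um3 = 8), nuc, params),
               "does not fit")
})
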