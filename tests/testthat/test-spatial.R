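test_that("pair classification follows the two-voxel / one-pixel rules", {
  px <- default_spacing()[["dx"]]

  # two shared voxels: colocalized
  a <- make_object(run_voxels(3, 8))
  b <- make_object(run_voxels(7, 12), label = 2L)
  expect_equal(classify_pair(a, b), "colocalized")

  # exactly one shared voxel: gap 0, adjacent
  b1 <- make_object(run_voxels(8, 12), label = 2L)
  expect_equal(classify_pair(a, b1), "adjacent")

  # touching without overlap: adjacent
  b2 <- make_object(run_voxels(9, 12), label = 2L)
  expect_equal(classify_pair(a, b2), "adjacent")

  # five-voxel in-plane gap: distant
  b3 <- make_object(run_voxels(14, 18), label = 2L)
  expect_equal(classify_pair(a, b3), "distant")

  # symmetry and totality over random toy pairs
  set.seed(41)
  for (i in 1:20) {
    va <- run_voxels(sample(1:10, 1), sample(11:14, 1), y = sample(3:8, 1))
    vb <- run_voxels(sample(1:10, 1), sample(11:14, 1), y = sample(3:8, 1))
    oa <- make_object(va); ob <- make_object(vb, label = 2L)
    cab <- classify_pair(oa, ob); cba <- classify_pair(ob, oa)
    expect_identical(cab, cba)
    expect_true(cab %in% c("colocalized", "adjacent", "distant"))
  }
})

test_that("adjacency uses the edge gap against one in-plane pixel", {
  a <- make_object(run_voxels(3, 6))
  # one empty voxel between edges: gap equals one pixel, not strictly less
  b <- make_object(run_voxels(8, 10), label = 2L)
  expect_equal(classify_pair(a, b), "distant")
  # a wider configured adjacency gap admits it
  expect_equal(classify_pair(a, b, adjacency_gap = 0.25), "adjacent")
  empty <- make_object(run_voxels(3, 6)[0, , drop = FALSE])
  expect_error(classify_pair(a, empty), "empty")
})

test_that("association counting consumes each object at most once", {
  # no cross-channel object within a pixel: zero associations
  a1 <- make_object(run_voxels(2, 4))
  b_far <- make_object(run_voxels(12, 14), label = 1L, channel = "b")
  expect_equal(count_associations(list(a1), list(b_far)), 0L)

  # one overlapping pair: one association
  b_on <- make_object(run_voxels(3, 5), label = 1L, channel = "b")
  expect_equal(count_associations(list(a1), list(b_on)), 1L)

  # two a-objects near one b-object: b consumed once
  a2 <- make_object(run_voxels(6, 7), label = 2L)
  expect_equal(count_associations(list(a1, a2), list(b_on)), 1L)

  # bounded by the smaller set over random toys
  set.seed(42)
  for (i in 1:10) {
    sa <- lapply(1:3, function(k)
      make_object(run_voxels(sample(1:14, 1), sample(15:18, 1),
                             y = sample(3:9, 1)), label = k))
    sb <- lapply(1:2, function(k)
      make_object(run_voxels(sample(1:14, 1), sample(15:18, 1),
                             y = sample(3:9, 1)), label = k, channel = "b"))
    expect_lte(count_associations(sa, sb), 2L)
  }
})

test_that("axis frame recovers orientation and rejects degenerate masks", {
  params <- sim_params()
  for (theta in c(0, 0.6, 2.2)) {
    an <- analytic_nucleus(theta = theta, params = params)
    hint <- c(cos(theta), sin(theta), 0)
    fr <- fit_axis_frame(an$obj, anterior_hint = hint)
    ang <- acos(min(1, abs(sum(fr$direction * hint)))) * 180 / pi
    expect_lt(ang, 3)
    expect_equal(fr$ap_length, 12, tolerance = 0.02)
  }

  # sphere: no dominant axis
  sph <- analytic_nucleus(semi_axes = c(1.5, 1.5, 1.5), params = params)
  expect_error(fit_axis_frame(sph$obj), "axis undefined")

  # without a hint the frame is flagged low-confidence
  an <- analytic_nucleus(theta = 0.3, params = params)
  expect_true(fit_axis_frame(an$obj)$low_confidence)
})

test_that("AP position maps poles to 0/100 and the centre to 50", {
  an <- analytic_nucleus(theta = 0.4, params = sim_params())
  hint <- c(cos(0.4), sin(0.4), 0)
  fr <- fit_axis_frame(an$obj, anterior_hint = hint)
  g <- an$geom

  post <- drop(spermfish3d:::.frame_to_xyz(g, -5.95, 0))
  ant <- drop(spermfish3d:::.frame_to_xyz(g, 5.95, 0))
  mid <- drop(spermfish3d:::.frame_to_xyz(g, 0, 0))
  expect_lt(ap_position(post, fr), 1.5)
  expect_gt(ap_position(ant, fr), 98.5)
  expect_equal(ap_position(mid, fr), 50, tolerance = 0.02)
})

test_that("ML position is 0 on the axis, ~50 mid-ray and ~100 at the border", {
  an <- analytic_nucleus(theta = 1.1, params = sim_params())
  hint <- c(cos(1.1), sin(1.1), 0)
  fr <- fit_axis_frame(an$obj, anterior_hint = hint)
  g <- an$geom

  on_axis <- drop(spermfish3d:::.frame_to_xyz(g, 1.2, 0))
  expect_lt(ml_position(on_axis, fr, an$obj), 1.5)

  halfway <- drop(spermfish3d:::.frame_to_xyz(g, 0, 3.5 / 2))
  expect_equal(ml_position(halfway, fr, an$obj), 50, tolerance = 2 / 50)

  near_border <- drop(spermfish3d:::.frame_to_xyz(g, 0, 3.5 * 0.985))
  expect_gt(ml_position(near_border, fr, an$obj), 96)

  outside <- drop(spermfish3d:::.frame_to_xyz(g, 0, 4.2))
  expect_error(ml_position(outside, fr, an$obj), "outside")
})

test_that("positions are invariant under in-plane rotation of the nucleus", {
  params <- sim_params()
  probe <- c(ap = 72, ml = 45)
  vals <- sapply(c(0.2, 0.2 + pi / 6, 0.2 + pi / 2), function(theta) {
    an <- analytic_nucleus(theta = theta, params = params)
    fr <- fit_axis_frame(an$obj, anterior_hint = c(cos(theta), sin(theta), 0))
    tmw <- spermfish3d:::.apml_to_frame(probe["ap"], probe["ml"], 0, an$geom)
    pt <- drop(spermfish3d:::.frame_to_xyz(an$geom, tmw[1], tmw[2], tmw[3]))
    c(ap = ap_position(pt, fr), ml = ml_position(pt, fr, an$obj))
  })
  expect_lt(diff(range(vals["ap", ])), 1.5)
  expect_lt(diff(range(vals["ml", ])), 2)
})

test_that("morphology classification applies a strict ratio threshold", {
  # toy voxel clouds with controlled second moments
  blob <- function(nx, ny, nz = 2L) {
    as.matrix(expand.grid(z = 1:nz, y = 1:ny, x = 1:nx))[, c("z", "y", "x")]
  }
  sp <- c(dz = 0.1, dy = 0.1, dx = 0.1)  # isotropic toy spacing
  round_obj <- make_object(blob(6, 6), dims = c(10L, 10L, 10L), spacing = sp)
  expect_equal(classify_morphology(round_obj), "round")
  long_obj <- make_object(blob(18, 6), dims = c(10L, 30L, 30L), spacing = sp)
  expect_equal(classify_morphology(long_obj), "elongated")

  # a ratio exactly at the threshold stays round (strict inequality)
  co <- voxel_coords(long_obj$voxels, sp)
  l <- sqrt(eigen(cov(co), symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(classify_morphology(long_obj, ratio_threshold = l[1] / l[2]),
               "round")

  # rendered shapes: sphere-like round, 3:1 elongated
  params <- sim_params()
  nuc <- render_nucleus(nucleus_spec(), params)
  seg_ct <- function(spec) {
    sig <- render_ct(spec, nuc, params)
    st <- image_stack(list(dna = spermfish3d:::.apply_noise(nuc$signal, params),
                           ct = spermfish3d:::.apply_noise(sig, params)),
                      params$spacing)
    cfg <- seg_config()
    segment_signals(st, "ct", segment_nucleus(st, cfg), cfg)[[1]]
  }
  set.seed(43)
  expect_equal(classify_morphology(
    seg_ct(ct_spec("ssc17", 50, 25, elongation_ratio = 1, volume_um3 = 3))),
    "round")
  expect_equal(classify_morphology(
    seg_ct(ct_spec("ssc13", 50, 25, shape = "elongated",
                   elongation_ratio = 3, volume_um3 = 8))),
    "elongated")
})

test_that("border distance equals the exhaustive minimum over border voxels", {
  # toy 9^3 mask with irregular shape
  mask <- array(FALSE, dim = c(9, 9, 9))
  mask[3:7, 2:8, 3:8] <- TRUE
  mask[5:7, 6:8, 6:8] <- FALSE
  sp <- c(dz = 0.2, dy = 0.1, dx = 0.1)
  vox <- arrayInd(which(mask), dim(mask))
  obj <- make_object(vox, dims = dim(mask), spacing = sp)
  obj$mask <- mask
  pt <- unname(voxel_coords(cbind(5L, 4L, 5L), sp)[1, ])

  # independent exhaustive search: all mask voxels with an out-of-mask
  # 6-neighbour, triple loop
  best <- Inf
  for (z in 1:9) for (y in 1:9) for (x in 1:9) {
    if (!mask[z, y, x]) next
    nb_out <- FALSE
    for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
      w <- c(z, y, x) + o
      if (any(w < 1) || any(w > 9) || !mask[w[1], w[2], w[3]]) { nb_out <- TRUE; break }
    }
    if (!nb_out) next
    co <- voxel_coords(cbind(z, y, x), sp)[1, ]
    best <- min(best, sqrt(sum((co - pt)^2)))
  }
  expect_equal(border_distance(pt, obj), best)

  # ellipsoid centre: nearest border along the depth axis
  an <- analytic_nucleus(params = sim_params())
  ctr <- an$geom$centre
  expect_equal(border_distance(ctr, an$obj), 1.5, tolerance = 0.244 / 1.5)
})

test_that("measure_nucleus is deterministic and degrades gracefully", {
  d <- demo_stack(seed = 301, carrier_fraction = 1)
  hint <- anterior_hint_of(d$manifest)
  r1 <- measure_nucleus(d$stack, seg_config(), anterior_hint = hint, id = "a")
  r2 <- measure_nucleus(d$stack, seg_config(), anterior_hint = hint, id = "a")
  expect_identical(r1, r2)

  # a carrier nucleus is never distant
  expect_true(r1$pair_category %in% c("colocalized", "adjacent"))

  # without CT channels the counts survive and positions are NA
  st2 <- image_stack(d$stack$channels[c("dna", "telomere")], d$stack$spacing)
  r3 <- measure_nucleus(st2, seg_config(), anterior_hint = hint)
  expect_false(is.na(r3$n_telomere_clusters))
  expect_true(is.na(r3$ssc13_ap_pct))
  expect_true(is.na(r3$pair_category))
})
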