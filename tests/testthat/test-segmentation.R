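test_that("auto threshold equals the exhaustive between-class-variance search", {
  set.seed(31)
  # bimodal 8-bit histograms of varying balance
  for (fg_frac in c(0.5, 0.1, 0.01)) {
    n <- 5000
    nfg <- max(2, round(n * fg_frac))
    v <- c(pmax(0, pmin(255, round(rnorm(n - nfg, 10, 3)))),
           pmax(0, pmin(255, round(rnorm(nfg, 150, 12)))))
    expect_equal(auto_threshold(as.integer(v)), oracle_otsu(v))
  }
  # arbitrary (non-bimodal) data still matches the exhaustive maximizer
  v <- as.integer(sample(0:255, 2000, TRUE, prob = (1:256)^1.5))
  expect_equal(auto_threshold(v), oracle_otsu(v))
})

test_that("auto threshold separates a bimodal image and is deterministic", {
  set.seed(32)
  v <- as.integer(c(round(rnorm(4000, 10, 3)), round(rnorm(400, 150, 10))))
  v <- pmax(0L, pmin(255L, v))
  t1 <- auto_threshold(v)
  expect_gt(t1, 10); expect_lt(t1, 150)
  expect_identical(auto_threshold(v), t1)
  expect_error(auto_threshold(rep(7L, 100)), "constant")
})

test_that("connected components match the brute-force flood fill", {
  set.seed(33)
  for (conn in c(6L, 18L, 26L)) {
    for (rep in 1:3) {
      mask <- array(runif(14 * 14 * 14) < 0.25, dim = c(14, 14, 14))
      lab <- spermfish3d:::cc_label3d(mask, dim(mask), conn)
      ref <- oracle_flood_fill(mask, conn)
      expect_equal(max(lab), max(ref))
      # identical partitions: the label maps agree up to renaming
      expect_equal(length(unique(paste(lab[mask], ref[mask]))), max(ref))
      expect_equal(sort(tabulate(lab[mask])), sort(tabulate(ref[mask])))
      # and background is untouched
      expect_true(all(lab[!mask] == 0L))
    }
  }
})

test_that("nucleus segmentation recovers the synthetic nucleus", {
  d <- demo_stack(seed = 201)
  nuc <- segment_nucleus(d$stack, seg_config())
  v_true <- 4 / 3 * pi * prod(d$manifest$semi_axes)
  expect_equal(nuc$volume_um3, v_true, tolerance = 0.05)

  # empty image is an explicit error
  zero <- image_stack(list(dna = array(0L, dim = c(4, 8, 8))))
  expect_error(segment_nucleus(zero, seg_config()), "empty nucleus|constant")

  # of two disjoint bright regions the larger is the nucleus
  arr <- array(0L, dim = c(5, 30, 30))
  arr[2:4, 3:12, 3:12] <- 200L   # large
  arr[2:3, 20:23, 20:23] <- 200L # small
  st <- image_stack(list(dna = arr))
  big <- segment_nucleus(st, seg_config(counterstain_mode = "manual"))
  expect_equal(big$n_voxels, 3L * 10L * 10L)
})

test_that("nucleus holes are filled", {
  arr <- array(0L, dim = c(5, 20, 20))
  arr[2:4, 4:15, 4:15] <- 200L
  arr[3, 8:10, 8:10] <- 0L   # internal cavity
  st <- image_stack(list(dna = arr))
  nuc <- segment_nucleus(st, seg_config(counterstain_mode = "manual"))
  expect_equal(nuc$n_voxels, 3L * 12L * 12L)
  expect_true(all(nuc$mask[3, 8:10, 8:10]))
})

test_that("signal objects are masked, size-filtered and volume-ordered", {
  arr <- array(0L, dim = c(6, 30, 30))
  # inside-nucleus objects: 3x3x2 = 18 voxels and 2x2x2 = 8 voxels
  arr[2:3, 5:7, 5:7] <- 200L
  arr[2:3, 15:16, 15:16] <- 200L
  # 4-voxel speck below the size filter
  arr[2, 20:21, 5:6] <- 200L
  dna <- array(0L, dim = c(6, 30, 30)); dna[1:6, 2:28, 2:28] <- 150L
  st <- image_stack(list(dna = dna, sig = arr))
  cfg <- seg_config(counterstain_mode = "manual")
  nuc <- segment_nucleus(st, cfg)
  objs <- segment_signals(st, "sig", nuc, cfg)
  expect_length(objs, 2)
  expect_equal(objs[[1]]$n_voxels, 18L)
  expect_equal(objs[[2]]$n_voxels, 8L)
  expect_equal(vapply(objs, `[[`, 1L, "label"), 1:2)

  # at exactly min_object_voxels - 1 the object is dropped
  arr2 <- array(0L, dim = c(6, 30, 30))
  arr2[2, 10, 10:13] <- 200L  # 4 voxels < default 5
  st2 <- image_stack(list(dna = dna, sig = arr2))
  expect_length(segment_signals(st2, "sig", nuc, cfg), 0)

  # signal outside the nucleus mask is ignored
  arr3 <- array(0L, dim = c(6, 30, 30))
  arr3[2:3, 29:30, 29:30] <- 200L
  st3 <- image_stack(list(dna = dna, sig = arr3))
  expect_length(segment_signals(st3, "sig", nuc, cfg), 0)
})

test_that("segmentation is deterministic and partitions the thresholded voxels", {
  d <- demo_stack(seed = 202)
  cfg <- seg_config(min_object_voxels = 1L)
  nuc1 <- segment_nucleus(d$stack, cfg)
  nuc2 <- segment_nucleus(d$stack, cfg)
  expect_identical(nuc1$voxels, nuc2$voxels)

  objs <- segment_signals(d$stack, "telomere", nuc1, cfg)
  objs2 <- segment_signals(d$stack, "telomere", nuc1, cfg)
  expect_identical(lapply(objs, `[[`, "voxels"), lapply(objs2, `[[`, "voxels"))

  # with no size filter, object voxels partition mask(channel) & mask(nucleus)
  thr <- cfg$manual_threshold
  expected_vox <- sum(d$stack$channels$telomere > thr & nuc1$mask)
  got <- do.call(rbind, lapply(objs, `[[`, "voxels"))
  expect_equal(nrow(got), expected_vox)
  expect_equal(nrow(unique(as.data.frame(got))), expected_vox)
})

test_that("projected counting agrees with 3D counting for separated clusters", {
  d <- demo_stack(seed = 203)
  cfg <- seg_config()
  nuc <- segment_nucleus(d$stack, cfg)
  n3 <- count_clusters(segment_signals(d$stack, "telomere", nuc, cfg))
  np <- count_clusters(segment_signals(d$stack, "telomere", nuc, cfg,
                                       project = TRUE))
  expect_equal(np, n3)
})
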