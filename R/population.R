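# Population-level ground-truth generation: per-nucleus manifests drawn from
# the study conditions, deterministic re-rendering of any manifest entry,
# and TIFF export of whole populations.

# Telomere cluster sizes: draw from {2,3,4} until fewer than 5 telomeres
# remain, then emit the remainder as one smaller cluster (a pair or a
# singleton). Totals are conserved by construction.
.draw_cluster_sizes <- function(total, weights) {
  sizes <- integer(0)
  rem <- total
  vals <- as.integer(names(weights))
  while (rem > max(vals)) {
    s <- sample(vals, 1L, prob = weights)
    sizes <- c(sizes, s)
    rem <- rem - s
  }
  if (rem > 0L) sizes <- c(sizes, rem)
  sizes
}

# Random composition of `total` items into `k` parts, each >= 1.
.random_composition <- function(total, k) {
  if (k == 1L) return(total)
  extra <- tabulate(sample.int(k, total - k, replace = TRUE), nbins = k)
  extra + 1L
}

# Rejection-place `k` cluster centres with a minimum in-plane separation
# from each other and from `avoid` (an optional 2-column (t, m) matrix with
# its own clearance). Returns a data frame of centres in both nucleus-frame
# and (ap, ml, azimuth) coordinates.
.place_cluster_centres <- function(k, geom, params, avoid = NULL,
                                   avoid_clearance = 0) {
  if (k == 0L) {
    return(data.frame(t = numeric(0), m = numeric(0), w = numeric(0),
                      ap_percent = numeric(0), ml_percent = numeric(0),
                      azimuth = numeric(0)))
  }
  acc <- matrix(numeric(0), ncol = 3)  # t, m, w
  apml <- matrix(numeric(0), ncol = 3) # ap, ml, az
  min_sep <- params$min_separation
  for (i in seq_len(k)) {
    ok <- FALSE
    for (try in 1:400) {
      ap <- runif(1, params$ap_range[1], params$ap_range[2])
      ml <- runif(1, 0, params$ml_max)
      az <- runif(1, 0, 2 * pi)
      if (abs(sin(az)) * ml / 100 > 0.7) next  # keep spots off the z border
      tmw <- .apml_to_frame(ap, ml, az, geom)
      if (nrow(acc) &&
          min(sqrt((acc[, 1] - tmw[1])^2 + (acc[, 2] - tmw[2])^2)) < min_sep)
        next
      if (!is.null(avoid) && nrow(avoid) &&
          min(sqrt((avoid[, 1] - tmw[1])^2 + (avoid[, 2] - tmw[2])^2)) <
          avoid_clearance)
        next
      acc <- rbind(acc, tmw)
      apml <- rbind(apml, c(ap, ml, az))
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place ", k, " clusters at separation ",
                  min_sep, " um")
  }
  data.frame(t = acc[, 1], m = acc[, 2], w = acc[, 3],
             ap_percent = apml[, 1], ml_percent = apml[, 2],
             azimuth = apml[, 3])
}

# Draw shape/orientation/semi-axes for one CT.
.draw_ct_shape <- function(name, p_elongated, params) {
  shape <- if (runif(1) < p_elongated) "elongated" else "round"
  ratio <- if (shape == "elongated")
    runif(1, params$elongated_ratio_range[1], params$elongated_ratio_range[2])
  else runif(1, params$round_ratio_range[1], params$round_ratio_range[2])
  phi <- if (shape == "elongated") runif(1, -pi / 6, pi / 6) else runif(1, 0, pi)
  ax <- .ct_semi_axes(params$ct_volume[[name]], ratio, params$ct_z_cap)
  list(name = name, shape = shape, ratio = ratio, phi = phi, ax = ax)
}

# Place one CT independently (used for the distant category and the
# gonosome): truncated-normal ap/ml around the supplied means, with
# containment retries that pull the territory toward the axis.
.place_ct_single <- function(shape, ap_mean, ap_sd, ml_mean, ml_sd, geom,
                             params) {
  ml_scale <- 1
  for (try in 1:120) {
    ap <- .rtnorm(1, ap_mean, ap_sd, 10, 90)
    ml <- .rtnorm(1, ml_mean * ml_scale, ml_sd, 0, 78)
    side <- sample(c(-1, 1), 1L)
    t0 <- (ap / 50 - 1) * geom$a
    m0 <- side * (ml / 100) * .cs_scale(t0, geom$a) * geom$b
    if (.ct_fits(t0, m0, shape$phi, shape$ax, geom))
      return(list(t = t0, m = m0, side = side))
    if (try %% 20 == 0) ml_scale <- ml_scale * 0.8
  }
  stop("could not place territory '", shape$name, "' inside the nucleus")
}

# Place the SSC13/SSC17 pair at a given true category. Proximal
# (colocalized/adjacent) pairs share one long-axis orientation and sit back
# to back along it — the natural configuration of a fused or contacting
# pair, and the configuration in which the designed surface gap is exact
# (tilted ellipses have no closed-form contact distance). Distant nuclei
# place the two territories independently, with separation certified by the
# ellipses' support functions (a separating slab of >= 0.6 um).
.place_ct_pair <- function(category, fused, geom, params) {
  pe <- if (fused) params$p_elongated$fused else params$p_elongated$control
  s13 <- .draw_ct_shape("ssc13", pe[["ssc13"]], params)
  s17 <- .draw_ct_shape("ssc17", pe[["ssc17"]], params)
  qe <- .ct_q_eff(params)
  px <- params$spacing[["dx"]]
  if (category == "distant") {
    p13 <- .place_ct_single(s13, params$ct_ap_mean, params$ct_ap_sd,
                            params$ct_ml_mean[["ssc13"]], params$ct_ml_sd,
                            geom, params)
    for (try in 1:120) {
      p17 <- .place_ct_single(s17, params$ct_ap_mean, params$ct_ap_sd,
                              params$ct_ml_mean[["ssc17"]], params$ct_ml_sd,
                              geom, params)
      dvec <- c(p17$t - p13$t, p17$m - p13$m)
      dist <- sqrt(sum(dvec^2))
      alpha <- atan2(dvec[2], dvec[1])
      gap <- dist -
        qe * .ct_support(alpha, s13$phi, s13$ax["la"], s13$ax["sb"]) -
        qe * .ct_support(alpha, s17$phi, s17$ax["la"], s17$ax["sb"])
      if (gap >= 0.6) return(list(s13 = s13, p13 = p13, s17 = s17, p17 = p17))
    }
    stop("could not place a distant SSC13/SSC17 pair")
  }
  ml_mean <- if (fused) params$fused_pair_ml_mean else params$control_pair_ml_mean
  for (try in 1:200) {
    ap <- .rtnorm(1, params$ct_ap_mean, params$ct_ap_sd, 15, 85)
    ml <- .rtnorm(1, ml_mean, params$ct_ml_sd, 0, 60)
    side <- sample(c(-1, 1), 1L)
    t0 <- (ap / 50 - 1) * geom$a
    m0 <- side * (ml / 100) * .cs_scale(t0, geom$a) * geom$b
    alpha <- runif(1, -pi / 5, pi / 5) + sample(c(0, pi), 1L)
    s13$phi <- s17$phi <- alpha
    la13 <- qe * s13$ax[["la"]]; la17 <- qe * s17$ax[["la"]]
    d <- if (category == "colocalized")
      la13 + la17 - params$pair_overlap_frac * min(la13, la17)
    else la13 + la17 + params$pair_contact_gap_px * px
    p13 <- list(t = t0 - d / 2 * cos(alpha), m = m0 - d / 2 * sin(alpha),
                side = side)
    p17 <- list(t = t0 + d / 2 * cos(alpha), m = m0 + d / 2 * sin(alpha),
                side = side)
    if (.ct_fits(p13$t, p13$m, s13$phi, s13$ax, geom) &&
        .ct_fits(p17$t, p17$m, s17$phi, s17$ax, geom))
      return(list(s13 = s13, p13 = p13, s17 = s17, p17 = p17))
  }
  stop("could not place a ", category, " SSC13/SSC17 pair")
}

.ct_row <- function(shape, place, geom) {
  apml <- .frame_to_apml(place$t, place$m, 0, geom)
  data.frame(name = shape$name, t = place$t, m = place$m, w = 0,
             phi = shape$phi, shape = shape$shape,
             elongation_ratio = shape$ratio,
             la = unname(shape$ax["la"]), sb = unname(shape$ax["sb"]),
             sc = unname(shape$ax["sc"]),
             ap_percent = unname(apml[, "ap"]),
             ml_percent = unname(apml[, "ml"]),
             stringsAsFactors = FALSE)
}

# Build the full ground-truth manifest of one nucleus. All randomness comes
# from `spec_seed`; `render_seed` governs the later image-noise stream so a
# manifest re-renders identically.
.nucleus_manifest <- function(id, spec_seed, render_seed, carrier_fraction,
                              params) {
  set.seed(spec_seed)
  carrier <- runif(1) < carrier_fraction
  gono <- sample(c("X", "Y"), 1L)
  spec <- nucleus_spec(params$semi_axes, theta = runif(1, 0, pi),
                       anterior_sign = sample(c(-1L, 1L), 1L))
  geom <- .stack_geometry(spec, params)

  # telomere clusters: totals conserved at the karyotype telomere count
  telomere_total <- if (carrier) 36L else 38L
  tsizes <- .draw_cluster_sizes(telomere_total, params$telomere_cluster_weights)
  tpos <- .place_cluster_centres(length(tsizes), geom, params)
  telo <- cbind(data.frame(channel = "telomere", member_count = tsizes),
                tpos)

  # chromocenters: AC6 loses one labelled centromere in fused gametes
  ac6_total <- if (carrier) 5L else 6L
  ac6_probs <- if (carrier) params$ac6_cluster_probs$fused
               else params$ac6_cluster_probs$control
  k_ac6 <- as.integer(sample(names(ac6_probs), 1L, prob = ac6_probs))
  rs2a_total <- 11L
  k_rs2a <- as.integer(sample(names(params$rs2a_cluster_probs), 1L,
                              prob = params$rs2a_cluster_probs))
  assoc_probs <- if (carrier) params$assoc_probs$fused
                 else params$assoc_probs$control
  n_assoc <- min(as.integer(sample(names(assoc_probs), 1L, prob = assoc_probs)),
                 k_ac6, k_rs2a)

  joint <- .place_cluster_centres(n_assoc, geom, params)
  ac6_rest <- .place_cluster_centres(k_ac6 - n_assoc, geom, params,
                                     avoid = as.matrix(joint[, c("t", "m")]),
                                     avoid_clearance = params$min_separation)
  avoid_rs <- rbind(as.matrix(joint[, c("t", "m")]),
                    as.matrix(ac6_rest[, c("t", "m")]))
  rs2a_rest <- .place_cluster_centres(k_rs2a - n_assoc, geom, params,
                                      avoid = avoid_rs,
                                      avoid_clearance = params$cross_channel_clearance)
  # associated RS2A clusters sit a fraction of a pixel off their AC6 partner
  joint_rs <- joint
  if (n_assoc > 0L) {
    shift_ang <- runif(n_assoc, 0, 2 * pi)
    joint_rs$t <- joint_rs$t + params$assoc_offset * cos(shift_ang)
    joint_rs$m <- joint_rs$m + params$assoc_offset * sin(shift_ang)
    apml <- .frame_to_apml(joint_rs$t, joint_rs$m, joint_rs$w, geom)
    joint_rs$ap_percent <- apml[, "ap"]; joint_rs$ml_percent <- apml[, "ml"]
    joint_rs$azimuth <- atan2(joint_rs$w, joint_rs$m)
  }
  ac6_sizes <- .random_composition(ac6_total, k_ac6)
  rs2a_sizes <- .random_composition(rs2a_total, k_rs2a)
  ac6 <- cbind(data.frame(channel = "ac6", member_count = ac6_sizes),
               rbind(joint, ac6_rest))
  rs2a <- cbind(data.frame(channel = "sscrs2a", member_count = rs2a_sizes),
                rbind(joint_rs, rs2a_rest))

  # SSC13/SSC17 territory pair
  cat_probs <- if (carrier) params$pair_category_probs$fused
               else params$pair_category_probs$control
  true_category <- sample(names(cat_probs), 1L, prob = cat_probs)
  pair <- .place_ct_pair(true_category, carrier, geom, params)

  # gonosome territory: round, position by identity
  gshape <- .draw_ct_shape(gono, 0, params)
  gshape$name <- "gonosome"
  gplace <- .place_ct_single(gshape, params$gono_ap_mean[[gono]], 15,
                             params$gono_ml_mean[[gono]], params$gono_sd,
                             geom, params)

  cts <- rbind(.ct_row(pair$s13, pair$p13, geom),
               .ct_row(pair$s17, pair$p17, geom),
               .ct_row(gshape, gplace, geom))
  cts$channel <- cts$name

  list(id = id, spec_seed = spec_seed, render_seed = render_seed,
       carrier = carrier, gonosome = gono,
       semi_axes = spec$semi_axes, theta = spec$theta,
       anterior_sign = spec$anterior_sign,
       telomere_total = telomere_total,
       clusters = rbind(telo, ac6, rs2a),
       cts = cts,
       true_category = true_category)
}

#' Generate a synthetic sperm-nucleus population with ground truth
#'
#' Draws `n` per-nucleus ground-truth manifests under the study conditions
#' in `params`. Each nucleus is a carrier of the 13;17 fusion with
#' probability `carrier_fraction` (0.5 for sperm of a heterozygous carrier
#' animal, 0 for a control animal). Carrier nuclei have 36 telomeres, 5
#' AC6-labelled centromeres and an SSC13/SSC17 pair drawn from the
#' fused-pair category distribution (never distant); non-carriers follow the
#' control distributions. A single master `seed` governs all randomness via
#' deterministic per-nucleus sub-streams, so the same call reproduces the
#' same population, and any single nucleus re-renders identically via
#' [simulate_nucleus()].
#'
#' @param n number of nuclei (>= 1).
#' @param carrier_fraction probability in \[0, 1\] that a nucleus carries the
#'   fusion.
#' @param params a [sim_params()].
#' @param seed integer master seed.
#' @return a `sperm_population`: list with `manifest` (per-nucleus ground
#'   truth), `index` (one-row-per-nucleus data frame of true values),
#'   `params`, `carrier_fraction`, `seed`.
#' @export
generate_population <- function(n, carrier_fraction = 0,
                                params = sim_params(), seed = 1L) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  if (!is.numeric(carrier_fraction) || length(carrier_fraction) != 1L ||
      is.na(carrier_fraction) || carrier_fraction < 0 || carrier_fraction > 1)
    stop("carrier_fraction must be a probability in [0, 1]")
  n <- as.integer(n)
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 8L, 2L * n), ncol = 2L)
  manifest <- lapply(seq_len(n), function(i) {
    # rejection placement can fail for rare crowded geometries; retry the
    # nucleus under a deterministically shifted sub-seed
    m <- NULL
    for (attempt in 0:4) {
      m <- tryCatch(
        .nucleus_manifest(sprintf("nuc%04d", i), seeds[i, 1] + attempt,
                          seeds[i, 2], carrier_fraction, params),
        error = function(e) NULL)
      if (!is.null(m)) break
    }
    if (is.null(m)) stop("could not generate nucleus ", i)
    m
  })
  pop <- structure(list(manifest = manifest, params = params,
                        carrier_fraction = carrier_fraction, seed = seed),
                   class = "sperm_population")
  pop$index <- manifest_index(pop)
  pop
}

#' @export
print.sperm_population <- function(x, ...) {
  cat(sprintf("sperm_population: %d nuclei, carrier fraction %.2f, seed %d\n",
              length(x$manifest), x$carrier_fraction, x$seed))
  cat(sprintf("  carriers drawn: %d; categories: %s\n",
              sum(x$index$carrier),
              paste(names(table(x$index$true_category)),
                    table(x$index$true_category), sep = "=", collapse = " ")))
  invisible(x)
}

#' Ground-truth index of a population
#'
#' One row per nucleus with the generator's true values: carrier flag,
#' gonosome identity, cluster counts per channel, the true SSC13/SSC17 pair
#' category, and true CT positions/morphologies. This is the reference the
#' recovery tests compare pipeline measurements against.
#'
#' @param pop a `sperm_population`.
#' @return data frame.
#' @export
manifest_index <- function(pop) {
  stopifnot(inherits(pop, "sperm_population"))
  rows <- lapply(pop$manifest, function(m) {
    ct <- function(nm, col) m$cts[m$cts$name == nm, col][1]
    data.frame(
      id = m$id, carrier = m$carrier, gonosome = m$gonosome,
      telomere_total = m$telomere_total,
      n_telomere_clusters = sum(m$clusters$channel == "telomere"),
      n_ac6_clusters = sum(m$clusters$channel == "ac6"),
      n_rs2a_clusters = sum(m$clusters$channel == "sscrs2a"),
      n_associations = NA_integer_,
      true_category = m$true_category,
      ssc13_ap_pct = ct("ssc13", "ap_percent"),
      ssc13_ml_pct = ct("ssc13", "ml_percent"),
      ssc13_shape = ct("ssc13", "shape"),
      ssc17_ap_pct = ct("ssc17", "ap_percent"),
      ssc17_ml_pct = ct("ssc17", "ml_percent"),
      ssc17_shape = ct("ssc17", "shape"),
      gonosome_ap_pct = ct("gonosome", "ap_percent"),
      gonosome_ml_pct = ct("gonosome", "ml_percent"),
      stringsAsFactors = FALSE)
  })
  idx <- do.call(rbind, rows)
  # association count is knowable from the manifest geometry
  idx$n_associations <- vapply(pop$manifest, .manifest_assoc_count,
                               integer(1), params = pop$params)
  idx
}

# Number of designed AC6/RS2A associations: cluster-centre pairs within the
# association offset (cross-channel pairs placed jointly).
.manifest_assoc_count <- function(m, params) {
  a <- m$clusters[m$clusters$channel == "ac6", c("t", "m")]
  b <- m$clusters[m$clusters$channel == "sscrs2a", c("t", "m")]
  if (!nrow(a) || !nrow(b)) return(0L)
  d <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j) {
    sqrt((a$t[i] - b$t[j])^2 + (a$m[i] - b$m[j])^2)
  })
  as.integer(sum(apply(d <= 2 * params$assoc_offset, 2, any)))
}

#' Render one manifest entry as a noisy multi-channel stack
#'
#' Deterministically re-renders a nucleus from its ground-truth manifest:
#' the DNA counterstain plus telomere, AC6, SSCRS2A, SSC13, SSC17 and
#' gonosome channels, with Poisson shot noise on signal and Gaussian read
#' noise on every voxel, clipped to the 8-bit range. The same manifest
#' always yields the same stack (noise is drawn under the manifest's
#' `render_seed`).
#'
#' @param m one element of `pop$manifest`.
#' @param params the population's [sim_params()].
#' @return an [image_stack()] with channels `dna`, `telomere`, `ac6`,
#'   `sscrs2a`, `ssc13`, `ssc17`, `gonosome`.
#' @export
simulate_nucleus <- function(m, params = sim_params()) {
  set.seed(m$render_seed)
  spec <- nucleus_spec(m$semi_axes, theta = m$theta,
                       anterior_sign = m$anterior_sign)
  nuc <- render_nucleus(spec, params)
  channels <- list(dna = nuc$signal)
  for (ch in c("telomere", "ac6", "sscrs2a")) {
    cl <- m$clusters[m$clusters$channel == ch, , drop = FALSE]
    channels[[ch]] <- render_spots(cl, nuc, params)
  }
  for (nm in c("ssc13", "ssc17", "gonosome")) {
    row <- m$cts[m$cts$name == nm, , drop = FALSE]
    if (!nrow(row)) next
    # use the stored semi-axes directly so truth and rendering agree exactly
    channels[[nm]] <- .add_ct_blob(array(0, dim = nuc$geom$dims), nuc$geom,
                                   row$t, row$m, row$phi,
                                   c(la = row$la, sb = row$sb, sc = row$sc),
                                   params$ct_amplitude)
  }
  out <- lapply(channels, .apply_noise, params = params)
  image_stack(out, params$spacing)
}

# background + Poisson shot noise on signal + Gaussian read noise, 8-bit.
.apply_noise <- function(signal, params) {
  v <- array(params$background, dim = dim(signal))
  idx <- which(signal > 1e-3)
  if (length(idx)) v[idx] <- v[idx] + rpois(length(idx), signal[idx])
  v <- v + round(rnorm(length(v), 0, params$read_noise_sd))
  v[v < 0] <- 0; v[v > 255] <- 255
  v
}

#' Write a population to disk
#'
#' One multi-channel TIFF (plus JSON spacing sidecar) per nucleus, a
#' `manifest.json` with the full ground truth, and an `index.csv` with the
#' per-nucleus true values.
#'
#' @param pop a `sperm_population`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of TIFF paths.
#' @export
write_population <- function(pop, dir) {
  stopifnot(inherits(pop, "sperm_population"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(pop$manifest, function(m) {
    stack <- simulate_nucleus(m, pop$params)
    p <- file.path(dir, paste0(m$id, ".tif"))
    write_stack(stack, p)
    p
  }, character(1))
  jsonlite::write_json(pop$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(pop$index, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(paths)
}
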