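# Per-nucleus spatial statistics: cluster counts, cross-channel chromocenter
# associations, the colocalized/adjacent/distant pair classifier, normalized
# antero-posterior (AP) and medio-lateral (ML) positions, territory
# morphology and centre-to-border distances.

#' Count signal clusters
#'
#' Each connected above-threshold component is one cluster (a chromocenter
#' or telomere cluster), so the count is simply the number of segmented
#' objects.
#'
#' @param objects list of `segmented_object`s from one channel of one
#'   nucleus.
#' @return integer count.
#' @export
count_clusters <- function(objects) length(objects)

#' Classify the spatial relation of two segmented objects
#'
#' The three-category rule for chromosome-territory pairs, in voxel terms:
#' *colocalized* if the two voxel sets share at least two voxels; otherwise
#' *adjacent* if the edge-to-edge gap is less than one in-plane pixel;
#' otherwise *distant*. The gap is the minimum distance between voxel
#' centres minus one in-plane pixel (floored at zero), so two objects
#' sharing exactly one voxel have gap zero and class adjacent. The
#' classification is symmetric and total.
#'
#' @param a,b non-empty `segmented_object`s from the same stack.
#' @param adjacency_gap gap threshold in um; default one in-plane pixel.
#' @return `"colocalized"`, `"adjacent"` or `"distant"`.
#' @export
classify_pair <- function(a, b, adjacency_gap = NULL) {
  stopifnot(inherits(a, "segmented_object"), inherits(b, "segmented_object"))
  if (a$n_voxels == 0L || b$n_voxels == 0L) stop("empty object")
  if (!identical(a$dims, b$dims)) stop("objects come from different stacks")
  px <- a$spacing[[3]]
  if (is.null(adjacency_gap)) adjacency_gap <- px
  lin_a <- .linear_index(a$voxels, a$dims)
  lin_b <- .linear_index(b$voxels, b$dims)
  if (length(intersect(lin_a, lin_b)) >= 2L) return("colocalized")
  dmin <- min_pair_dist(voxel_coords(a$voxels, a$spacing),
                        voxel_coords(b$voxels, b$spacing))
  gap <- max(0, dmin - px)
  if (gap < adjacency_gap) "adjacent" else "distant"
}

.linear_index <- function(vox, dims) {
  (vox[, 1] - 1) + dims[1] * ((vox[, 2] - 1) + dims[2] * (vox[, 3] - 1))
}

#' Count cross-channel chromocenter associations
#'
#' Number of cross-channel object pairs classified colocalized or adjacent,
#' with each object consumed by at most one association. Pairs are matched
#' greedily by smallest gap (distance between voxel sets), ties broken by
#' the smaller object labels. The count is bounded by
#' `min(length(set_a), length(set_b))`.
#'
#' @param set_a,set_b lists of `segmented_object`s from two channels of one
#'   nucleus.
#' @param adjacency_gap gap threshold in um; default one in-plane pixel.
#' @return integer association count.
#' @export
count_associations <- function(set_a, set_b, adjacency_gap = NULL) {
  if (!length(set_a) || !length(set_b)) return(0L)
  cand <- list()
  for (i in seq_along(set_a)) {
    for (j in seq_along(set_b)) {
      cat_ij <- classify_pair(set_a[[i]], set_b[[j]], adjacency_gap)
      if (cat_ij == "distant") next
      d <- min_pair_dist(voxel_coords(set_a[[i]]$voxels, set_a[[i]]$spacing),
                         voxel_coords(set_b[[j]]$voxels, set_b[[j]]$spacing))
      cand[[length(cand) + 1L]] <- c(i = i, j = j, d = d)
    }
  }
  if (!length(cand)) return(0L)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, "d"], cand[, "i"], cand[, "j"]), , drop = FALSE]
  used_a <- used_b <- integer(0)
  n <- 0L
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, "i"]; j <- cand[r, "j"]
    if (i %in% used_a || j %in% used_b) next
    used_a <- c(used_a, i); used_b <- c(used_b, j)
    n <- n + 1L
  }
  n
}

#' Fit the antero-posterior axis frame of a nucleus
#'
#' The AP direction is the dominant principal axis of the nucleus voxel
#' cloud in physical coordinates. The origin is the most posterior nucleus
#' voxel; AP positions are measured from it. The anterior end is
#' disambiguated by `anterior_hint` (a direction vector, e.g. from a
#' generator manifest); without a hint the sign is fixed deterministically
#' (positive x component) and flagged low-confidence, since a symmetric
#' ellipsoid offers no intrinsic anterior cue.
#'
#' A mask with no dominant axis (axis-length ratio below 1.1, e.g. a
#' sphere) has no defined AP axis and raises an error.
#'
#' @param nucleus output of [segment_nucleus()].
#' @param anterior_hint optional length-3 vector `(x, y, z)` pointing
#'   anteriorly.
#' @return an `axis_frame`: `origin` (posterior extreme, um), `direction`
#'   (anterior unit vector), `ap_length` (um).
#' @export
fit_axis_frame <- function(nucleus, anterior_hint = NULL) {
  stopifnot(inherits(nucleus, "segmented_object"))
  if (nucleus$n_voxels < 10L) stop("nucleus too small to fit an axis")
  coords <- voxel_coords(nucleus$voxels, nucleus$spacing)
  ev <- eigen(cov(coords), symmetric = TRUE)
  lens <- sqrt(pmax(ev$values, 0))
  if (lens[2] <= 0 || lens[1] / lens[2] < 1.1)
    stop("axis undefined: mask has no dominant principal axis")
  u <- ev$vectors[, 1]
  low_confidence <- FALSE
  if (!is.null(anterior_hint)) {
    if (sum(u * anterior_hint) < 0) u <- -u
  } else {
    nz <- which(abs(u) > 1e-12)[1]
    if (u[nz] < 0) u <- -u
    low_confidence <- TRUE
  }
  proj <- coords %*% u
  frame <- list(origin = coords[which.min(proj), ],
                centre = colMeans(coords),
                direction = u,
                ap_length = max(proj) - min(proj),
                min_proj = min(proj),
                low_confidence = low_confidence)
  class(frame) <- "axis_frame"
  frame
}

#' Normalized antero-posterior position
#'
#' Projects a point onto the AP axis and scales by the axis length:
#' 0% at the posterior pole, 100% at the anterior pole, clipped to
#' \[0, 100\].
#'
#' @param point physical coordinates `(x, y, z)` in um (e.g. a CT centroid).
#' @param frame an `axis_frame` from [fit_axis_frame()].
#' @return AP position in percent.
#' @export
ap_position <- function(point, frame) {
  stopifnot(inherits(frame, "axis_frame"))
  p <- sum(point * frame$direction)
  min(100, max(0, 100 * (p - frame$min_proj) / frame$ap_length))
}

#' Normalized medio-lateral position
#'
#' Unsigned radial position: 0% on the AP axis, 100% at the nuclear border.
#' The point is dropped perpendicularly onto the AP axis line (foot `a`);
#' the ray from `a` through the point is marched through the nucleus mask
#' to the last interior position `b`, and the position is
#' `100 * |point - a| / |b - a|`. The axis is not lateralized: left and
#' right map to the same coordinate.
#'
#' @param point physical coordinates `(x, y, z)` um; must lie inside the
#'   nucleus mask.
#' @param frame an `axis_frame`.
#' @param nucleus output of [segment_nucleus()] (provides the mask).
#' @return ML position in percent, clipped to \[0, 100\].
#' @export
ml_position <- function(point, frame, nucleus) {
  stopifnot(inherits(frame, "axis_frame"), inherits(nucleus, "segmented_object"))
  if (!.point_in_mask(point, nucleus)) stop("point lies outside the nucleus mask")
  # anchor the axis line at the voxel-cloud centroid: unlike the extreme
  # voxel it lies on the principal line by construction, and the foot of
  # the perpendicular is then invariant to the anterior/posterior choice
  t <- sum((point - frame$centre) * frame$direction)
  foot <- frame$centre + t * frame$direction
  r <- point - foot
  rad <- sqrt(sum(r^2))
  if (rad < 1e-9) return(0)
  dir <- r / rad
  step <- min(nucleus$spacing) / 2
  # march outward from the point to the last in-mask position
  b <- point
  k <- 1
  max_extent <- sum(nucleus$dims * nucleus$spacing[c("dz", "dy", "dx")])
  while (k * step < max_extent) {
    p <- point + k * step * dir
    if (!.point_in_mask(p, nucleus)) break
    b <- p
    k <- k + 1
  }
  border_rad <- sqrt(sum((b - foot)^2))
  min(100, max(0, 100 * rad / border_rad))
}

.point_in_mask <- function(point, nucleus) {
  sp <- nucleus$spacing
  iz <- round(point[3] / sp[["dz"]]) + 1
  iy <- round(point[2] / sp[["dy"]]) + 1
  ix <- round(point[1] / sp[["dx"]]) + 1
  d <- nucleus$dims
  if (iz < 1 || iz > d[1] || iy < 1 || iy > d[2] || ix < 1 || ix > d[3])
    return(FALSE)
  nucleus$mask[iz, iy, ix]
}

#' Classify territory morphology as round or elongated
#'
#' Principal second-moment axis lengths of the object's voxel cloud in
#' physical coordinates; elongated iff largest / second-largest axis length
#' strictly exceeds `ratio_threshold` (default 1.5), else round (a ratio
#' exactly at the threshold is round).
#'
#' @param ct a `segmented_object`.
#' @param ratio_threshold strict elongation cutoff.
#' @return `"round"` or `"elongated"`.
#' @export
classify_morphology <- function(ct, ratio_threshold = 1.5) {
  stopifnot(inherits(ct, "segmented_object"))
  if (ct$n_voxels < 4L) return("round")
  coords <- voxel_coords(ct$voxels, ct$spacing)
  lens <- sqrt(pmax(eigen(cov(coords), symmetric = TRUE,
                          only.values = TRUE)$values, 0))
  if (lens[2] < 1e-9) return("elongated")
  if (lens[1] / lens[2] > ratio_threshold) "elongated" else "round"
}

#' Distance from a point to the nuclear border
#'
#' Minimum physical distance from the point (typically a CT centroid) to
#' any background-adjacent nucleus voxel (6-neighbourhood border,
#' stack-boundary voxels included).
#'
#' @param point physical coordinates `(x, y, z)` um inside the nucleus.
#' @param nucleus output of [segment_nucleus()].
#' @return distance in um.
#' @export
border_distance <- function(point, nucleus) {
  stopifnot(inherits(nucleus, "segmented_object"))
  if (!.point_in_mask(point, nucleus)) stop("point lies outside the nucleus mask")
  bv <- .border_voxels(nucleus$mask)
  coords <- voxel_coords(bv, nucleus$spacing)
  sqrt(min((coords[, 1] - point[1])^2 + (coords[, 2] - point[2])^2 +
             (coords[, 3] - point[3])^2))
}

# Voxels of the mask with at least one 6-neighbour outside it (or on the
# array boundary).
.border_voxels <- function(mask) {
  d <- dim(mask)
  interior <- mask
  shift <- function(m, axis, by) {
    out <- array(FALSE, dim = d)
    if (axis == 1) {
      if (by == 1) out[2:d[1], , ] <- m[1:(d[1] - 1), , ]
      else out[1:(d[1] - 1), , ] <- m[2:d[1], , ]
    } else if (axis == 2) {
      if (by == 1) out[, 2:d[2], ] <- m[, 1:(d[2] - 1), ]
      else out[, 1:(d[2] - 1), ] <- m[, 2:d[2], ]
    } else {
      if (by == 1) out[, , 2:d[3]] <- m[, , 1:(d[3] - 1)]
      else out[, , 1:(d[3] - 1)] <- m[, , 2:d[3]]
    }
    out
  }
  for (axis in 1:3) for (by in c(1, -1))
    interior <- interior & shift(mask, axis, by)
  arrayInd(which(mask & !interior), d)
}

#' Measure one nucleus end to end
#'
#' Runs the full per-nucleus pipeline on a stack: nucleus segmentation,
#' axis-frame fit, spot-cluster counts for the telomere and centromeric
#' channels, AC6/SSCRS2A association count, and for every
#' chromosome-territory channel present (`ssc13`, `ssc17`, `gonosome`) the
#' largest object's AP/ML position, morphology class and border distance,
#' plus the SSC13/SSC17 pair category. Channels absent from the stack
#' yield `NA` fields; counts are always populated for the channels present.
#' Deterministic for a fixed stack and configuration.
#'
#' @param stack an [image_stack()].
#' @param cfg a [seg_config()].
#' @param anterior_hint optional anterior direction vector for the axis
#'   frame (e.g. from the generator manifest).
#' @param id nucleus identifier copied into the record.
#' @return one-row data frame (a nucleus record).
#' @export
measure_nucleus <- function(stack, cfg = seg_config(), anterior_hint = NULL,
                            id = NA_character_) {
  stopifnot(inherits(stack, "image_stack"))
  nucleus <- segment_nucleus(stack, cfg)
  frame <- fit_axis_frame(nucleus, anterior_hint)
  rec <- data.frame(id = id,
                    nucleus_volume_um3 = nucleus$volume_um3,
                    ap_length_um = frame$ap_length,
                    stringsAsFactors = FALSE)

  spot_channels <- c(telomere = "n_telomere_clusters",
                     ac6 = "n_ac6_clusters",
                     sscrs2a = "n_rs2a_clusters")
  objs <- list()
  for (ch in names(spot_channels)) {
    col <- spot_channels[[ch]]
    if (ch %in% names(stack$channels)) {
      objs[[ch]] <- segment_signals(stack, ch, nucleus, cfg)
      n3d <- if (cfg$count_mode == "projected")
        count_clusters(segment_signals(stack, ch, nucleus, cfg, project = TRUE))
      else count_clusters(objs[[ch]])
      rec[[col]] <- n3d
    } else rec[[col]] <- NA_integer_
  }
  rec$n_associations <- if (all(c("ac6", "sscrs2a") %in% names(objs)))
    count_associations(objs$ac6, objs$sscrs2a, cfg$adjacency_gap)
  else NA_integer_

  ct_objs <- list()
  for (ch in c("ssc13", "ssc17", "gonosome")) {
    pre <- ch
    if (ch %in% names(stack$channels)) {
      sig <- segment_signals(stack, ch, nucleus, cfg)
      if (length(sig)) {
        obj <- sig[[1]]
        ct_objs[[ch]] <- obj
        rec[[paste0(pre, "_ap_pct")]] <- ap_position(obj$centroid, frame)
        rec[[paste0(pre, "_ml_pct")]] <- ml_position(obj$centroid, frame, nucleus)
        rec[[paste0(pre, "_morphology")]] <-
          classify_morphology(obj, cfg$ratio_threshold)
        rec[[paste0(pre, "_border_um")]] <- border_distance(obj$centroid, nucleus)
        next
      }
    }
    rec[[paste0(pre, "_ap_pct")]] <- NA_real_
    rec[[paste0(pre, "_ml_pct")]] <- NA_real_
    rec[[paste0(pre, "_morphology")]] <- NA_character_
    rec[[paste0(pre, "_border_um")]] <- NA_real_
  }
  rec$pair_category <- if (all(c("ssc13", "ssc17") %in% names(ct_objs)))
    classify_pair(ct_objs$ssc13, ct_objs$ssc17, cfg$adjacency_gap)
  else NA_character_
  rec
}

#' Measure every nucleus of a synthetic population
#'
#' Renders each manifest entry with [simulate_nucleus()] (one stack in
#' memory at a time), measures it with [measure_nucleus()] using the
#' manifest's anterior direction as the axis hint, and binds the records.
#'
#' @param pop a `sperm_population` from [generate_population()].
#' @param cfg a [seg_config()].
#' @param verbose print progress every 50 nuclei.
#' @return data frame with one row per nucleus, including the true carrier
#'   flag for downstream grouping.
#' @export
measure_population <- function(pop, cfg = seg_config(), verbose = FALSE) {
  stopifnot(inherits(pop, "sperm_population"))
  rows <- vector("list", length(pop$manifest))
  for (i in seq_along(pop$manifest)) {
    m <- pop$manifest[[i]]
    stack <- simulate_nucleus(m, pop$params)
    hint <- m$anterior_sign * c(cos(m$theta), sin(m$theta), 0)
    rec <- measure_nucleus(stack, cfg, anterior_hint = hint, id = m$id)
    rec$carrier <- m$carrier
    rows[[i]] <- rec
    if (verbose && i %% 50 == 0)
      message("measured ", i, "/", length(pop$manifest), " nuclei")
  }
  do.call(rbind, rows)
}

#' Measure stacks stored on disk
#'
#' Applies [measure_nucleus()] to every `.tif` stack in a directory (as
#' written by [write_population()]).
#'
#' @param dir directory of TIFF stacks with spacing sidecars.
#' @param cfg a [seg_config()].
#' @param spacing optional spacing override passed to [read_stack()].
#' @return data frame of nucleus records.
#' @export
measure_stacks <- function(dir, cfg = seg_config(), spacing = NULL) {
  paths <- sort(list.files(dir, pattern = "\\.tif$", full.names = TRUE))
  if (!length(paths)) stop("no .tif stacks in ", dir)
  rows <- lapply(paths, function(p) {
    stack <- read_stack(p, spacing = spacing)
    measure_nucleus(stack, cfg, id = sub("\\.tif$", "", basename(p)))
  })
  do.call(rbind, rows)
}
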