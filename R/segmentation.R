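# Object detection by global intensity thresholding and 3D
# connected-component labelling, mirroring the interactive
# threshold-and-inspect workflow of confocal FISH quantification software:
# all objects are voxels above a globally set per-channel threshold, with
# the threshold either fixed by the user or chosen automatically.

#' Segmentation configuration
#'
#' @param threshold_mode `"manual"` (a globally set per-channel threshold,
#'   the workflow the pipeline mirrors) or `"auto"`
#'   (between-class-variance maximizing threshold, see [auto_threshold()]).
#' @param manual_threshold intensity in \[0, 255\]; either a single value or
#'   a named per-channel vector. Voxels strictly above it are foreground.
#'   The default 80 sits midway between the generator's background (10) and
#'   signal plateau (150).
#' @param counterstain_mode threshold mode for the DNA counterstain; the
#'   nucleus occupies a large voxel fraction so the automatic threshold is
#'   reliable there and is the default.
#' @param min_object_voxels signal objects smaller than this are discarded
#'   (single-voxel noise suppression; the nucleus itself is never filtered).
#' @param connectivity 6, 18 or 26 (default 26: clusters are isotropic in
#'   physical space and the axial spacing is coarse, so stricter
#'   connectivity would split axially adjacent voxels).
#' @param count_mode count spot clusters on the full 3D stack (`"3d"`) or on
#'   the z maximum projection (`"projected"`).
#' @param adjacency_gap edge-to-edge gap (um) below which two territories
#'   are called adjacent; defaults to one in-plane pixel (0.093 um).
#' @param ratio_threshold principal-axis ratio above which a territory is
#'   classed elongated.
#' @param central_cutoff ML% below which a territory counts as central.
#' @param counterstain name of the counterstain channel.
#' @return a `seg_config` list.
#' @export
seg_config <- function(threshold_mode = c("manual", "auto"),
                       manual_threshold = 80,
                       counterstain_mode = c("auto", "manual"),
                       min_object_voxels = 5L,
                       connectivity = 26L,
                       count_mode = c("3d", "projected"),
                       adjacency_gap = NULL,
                       ratio_threshold = 1.5,
                       central_cutoff = 50,
                       counterstain = "dna") {
  threshold_mode <- match.arg(threshold_mode)
  counterstain_mode <- match.arg(counterstain_mode)
  count_mode <- match.arg(count_mode)
  if (any(manual_threshold < 0 | manual_threshold > 255))
    stop("manual_threshold must lie in [0, 255]")
  if (min_object_voxels < 1L) stop("min_object_voxels must be >= 1")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  structure(list(threshold_mode = threshold_mode,
                 manual_threshold = manual_threshold,
                 counterstain_mode = counterstain_mode,
                 min_object_voxels = as.integer(min_object_voxels),
                 connectivity = as.integer(connectivity),
                 count_mode = count_mode,
                 adjacency_gap = adjacency_gap,
                 ratio_threshold = ratio_threshold,
                 central_cutoff = central_cutoff,
                 counterstain = counterstain),
            class = "seg_config")
}

.channel_threshold <- function(stack, channel, cfg, mode) {
  if (mode == "auto") return(auto_threshold(stack, channel))
  mt <- cfg$manual_threshold
  if (!is.null(names(mt)) && channel %in% names(mt)) mt <- mt[[channel]]
  else mt <- mt[[1]]
  as.numeric(mt)
}

#' Automatic global threshold (between-class variance criterion)
#'
#' Exhaustively maximizes the between-class variance of the 8-bit intensity
#' histogram over all 256 split levels and returns the maximizing level
#' `t`; foreground is `intensity > t`. Reproducible: identical inputs give
#' identical thresholds (ties resolve to the lowest level). This is the
#' automated stand-in for a user's globally set threshold.
#'
#' @param stack an [image_stack()] (or a bare integer array/vector of
#'   intensities in 0-255).
#' @param channel channel name when `stack` is an `image_stack`.
#' @return integer threshold level in 0-254.
#' @export
auto_threshold <- function(stack, channel = NULL) {
  v <- if (inherits(stack, "image_stack")) {
    if (is.null(channel) || !channel %in% names(stack$channels))
      stop("channel not found")
    stack$channels[[channel]]
  } else stack
  v <- as.integer(v)
  counts <- tabulate(v + 1L, nbins = 256L)
  p <- counts / sum(counts)
  lev <- 0:255
  w0 <- cumsum(p)                 # P(intensity <= t), t = 0..255
  mu <- cumsum(p * lev)           # first moment up to t
  muT <- mu[256]
  t_all <- 1:255                  # split after level t-1 (threshold t-1)
  w <- w0[t_all]
  valid <- w > 0 & w < 1
  if (!any(valid)) stop("constant channel: no threshold separates two classes")
  sb <- (muT * w - mu[t_all])^2 / (w * (1 - w))
  sb[!valid] <- -Inf
  as.integer(t_all[which.max(sb)] - 1L)
}

.new_segmented_object <- function(label, channel, voxels, dims, spacing) {
  coords <- voxel_coords(voxels, spacing)
  structure(list(label = as.integer(label), channel = channel,
                 voxels = voxels,
                 centroid = colMeans(coords),
                 volume_um3 = nrow(voxels) * prod(spacing),
                 n_voxels = nrow(voxels),
                 dims = dims, spacing = spacing),
            class = "segmented_object")
}

#' @export
print.segmented_object <- function(x, ...) {
  cat(sprintf(
    "segmented_object %d (%s): %d voxels, %.3f um^3, centroid (%.2f, %.2f, %.2f) um\n",
    x$label, x$channel, x$n_voxels, x$volume_um3,
    x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

# Rebuild the logical mask of an object.
.object_mask <- function(obj) {
  m <- array(FALSE, dim = obj$dims)
  m[obj$voxels] <- TRUE
  m
}

# Split a label array into a list of voxel-index matrices, one per label,
# ordered by label.
.label_voxels <- function(lab) {
  pos <- which(lab > 0L)
  if (!length(pos)) return(list())
  idx <- arrayInd(pos, dim(lab))
  split.data.frame(idx, lab[pos])
}

# Fill holes in a binary mask: slice-wise in 2D, then in 3D. A hole is a
# background component not connected to the array border.
.fill_holes <- function(mask) {
  d <- dim(mask)
  # slice-wise
  for (z in seq_len(d[1])) {
    sl <- array(mask[z, , ], dim = c(1L, d[2], d[3]))
    lab <- cc_label3d(!sl, dim(sl), 6L)
    border <- unique(c(lab[1, 1, ], lab[1, d[2], ], lab[1, , 1], lab[1, , d[3]]))
    hole <- lab > 0L & !(lab %in% border)
    if (any(hole)) {
      sl[hole] <- TRUE
      mask[z, , ] <- sl[1, , ]
    }
  }
  # 3D
  lab <- cc_label3d(!mask, d, 6L)
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                     lab[, , 1], lab[, , d[3]]))
  hole <- lab > 0L & !(lab %in% border)
  if (any(hole)) mask[hole] <- TRUE
  mask
}

#' Segment the nucleus from the counterstain channel
#'
#' Thresholds the counterstain, labels connected components and returns the
#' largest as the nucleus, with holes filled slice-wise and then in 3D.
#' Exactly one nucleus per stack is assumed.
#'
#' @param stack an [image_stack()].
#' @param cfg a [seg_config()].
#' @return a `segmented_object` with an additional `mask` element (logical
#'   array) used by downstream positional measures.
#' @export
segment_nucleus <- function(stack, cfg = seg_config()) {
  stopifnot(inherits(stack, "image_stack"))
  ch <- cfg$counterstain
  if (!ch %in% names(stack$channels))
    stop("counterstain channel '", ch, "' not present")
  thr <- .channel_threshold(stack, ch, cfg, cfg$counterstain_mode)
  mask <- stack$channels[[ch]] > thr
  if (!any(mask)) stop("empty nucleus: no voxels above threshold ", thr)
  lab <- cc_label3d(mask, stack$dim, cfg$connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  mask <- .fill_holes(lab == keep)
  vox <- arrayInd(which(mask), stack$dim)
  obj <- .new_segmented_object(1L, ch, vox, stack$dim, stack$spacing)
  obj$mask <- mask
  obj$threshold <- thr
  obj
}

#' Segment signal objects within the nucleus
#'
#' Connected components of above-threshold voxels restricted to the nucleus
#' mask, filtered by `min_object_voxels` and sorted by decreasing volume
#' (labels reassigned 1..k in that order, ties broken by first-voxel raster
#' order, so labelling is deterministic).
#'
#' @param stack an [image_stack()].
#' @param channel signal channel name.
#' @param nucleus output of [segment_nucleus()].
#' @param cfg a [seg_config()].
#' @param project if `TRUE`, collapse the thresholded mask along z before
#'   labelling (spot counting on the 2D projection).
#' @return list of `segmented_object`s (possibly empty).
#' @export
segment_signals <- function(stack, channel, nucleus, cfg = seg_config(),
                            project = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  if (!channel %in% names(stack$channels))
    stop("channel '", channel, "' not present")
  thr <- .channel_threshold(stack, channel, cfg, cfg$threshold_mode)
  mask <- stack$channels[[channel]] > thr & nucleus$mask
  if (project) {
    flat <- apply(mask, c(2, 3), any)
    mask <- array(flat, dim = c(1L, dim(flat)))
  }
  lab <- cc_label3d(mask, dim(mask), cfg$connectivity)
  groups <- .label_voxels(lab)
  groups <- groups[vapply(groups, nrow, 1L) >= cfg$min_object_voxels]
  if (!length(groups)) return(list())
  ord <- order(-vapply(groups, nrow, 1L), as.integer(names(groups)))
  groups <- groups[ord]
  lapply(seq_along(groups), function(i) {
    .new_segmented_object(i, channel, as.matrix(groups[[i]]), dim(mask),
                          stack$spacing)
  })
}
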