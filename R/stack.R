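# Multi-channel anisotropic 3D image stacks and their TIFF representation.
#
# Axis conventions, used everywhere in the package:
#   * voxel arrays have dim = (nz, ny, nx) and are indexed [z, y, x];
#   * physical coordinates are (x, y, z) in um with
#     coordinate = (index - 1) * spacing, i.e. 0-based voxel origins;
#   * spacing is named (dz, dy, dx) in um; all distances are um.

#' Default acquisition voxel spacing
#'
#' The confocal acquisition grid of the study: 0.093 um in-plane and
#' 0.244 um between planes, 8-bit per channel.
#' @return named numeric `c(dz, dy, dx)` in um.
#' @export
default_spacing <- function() c(dz = 0.244, dy = 0.093, dx = 0.093)

#' Construct a multi-channel image stack
#'
#' @param channels named list of 3D numeric/integer arrays with identical
#'   `dim = c(nz, ny, nx)`; intensities must lie in the 8-bit range 0-255.
#' @param spacing per-axis voxel size `c(dz, dy, dx)` in um, strictly
#'   positive.
#' @return an `image_stack` object.
#' @export
image_stack <- function(channels, spacing = default_spacing()) {
  stopifnot(is.list(channels), length(channels) >= 1L)
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("channels must be a named list")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive voxel sizes (dz, dy, dx)")
  names(spacing) <- c("dz", "dy", "dx")
  d <- dim(channels[[1]])
  if (length(d) != 3L) stop("each channel must be a 3D array (z, y, x)")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!identical(dim(ch), d)) stop("channel dimensions differ")
    rng <- range(ch)
    if (rng[1] < 0 || rng[2] > 255)
      stop("channel '", nm, "' has intensities outside [0, 255]")
    storage.mode(ch) <- "integer"
    channels[[nm]] <- ch
  }
  structure(list(channels = channels, spacing = spacing, dim = d),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image_stack: %d x %d x %d voxels (z,y,x), %d channel(s)\n",
              x$dim[1], x$dim[2], x$dim[3], length(x$channels)))
  cat(sprintf("  spacing (um): dz=%.3f dy=%.3f dx=%.3f\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Physical coordinates of voxel indices
#'
#' @param idx n x 3 integer matrix of 1-based voxel indices `(z, y, x)`.
#' @param spacing voxel size `c(dz, dy, dx)` in um.
#' @return n x 3 numeric matrix of `(x, y, z)` coordinates in um.
#' @export
voxel_coords <- function(idx, spacing) {
  idx <- rbind(idx)
  cbind(x = (idx[, 3] - 1) * spacing[3],
        y = (idx[, 2] - 1) * spacing[2],
        z = (idx[, 1] - 1) * spacing[1])
}

.sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write an image stack as a multi-frame 8-bit TIFF
#'
#' Frames are stored channel-major (all z planes of channel 1, then channel
#' 2, ...). Because plain TIFF has no standard slot for axial spacing or
#' channel names, a JSON sidecar (same basename, `.json`) records spacing,
#' dimensions and channel order; [read_stack()] uses it to reassemble the
#' stack bit-exactly.
#'
#' @param stack an [image_stack()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  nz <- stack$dim[1]
  frames <- vector("list", nz * length(stack$channels))
  i <- 0L
  for (ch in stack$channels) {
    for (z in seq_len(nz)) {
      i <- i + 1L
      frames[[i]] <- ch[z, , ] / 255
    }
  }
  tiff::writeTIFF(frames, path, bits.per.sample = 8L, compression = "none")
  jsonlite::write_json(
    list(dim = stack$dim, spacing_um = unname(stack$spacing),
         channels = names(stack$channels)),
    .sidecar_path(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a multi-frame TIFF stack
#'
#' Spacing precedence: an explicit `spacing` argument overrides the JSON
#' sidecar written by [write_stack()]; with neither available the spacing is
#' unknown and reading fails with an error naming the argument. Without a
#' sidecar the frames are interpreted as a single channel unless
#' `channel_names` and the implied plane count are supplied.
#'
#' @param path `.tif` path.
#' @param spacing optional `c(dz, dy, dx)` um override.
#' @param channel_names optional channel names when no sidecar exists.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, spacing = NULL, channel_names = NULL) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!length(frames)) stop("no frames in ", path)
  meta <- NULL
  sp <- .sidecar_path(path)
  if (file.exists(sp)) meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (!is.null(spacing)) {
    spacing <- as.numeric(spacing)
    if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
      stop("'spacing' override must be three positive values (dz, dy, dx)")
  } else if (!is.null(meta)) {
    spacing <- meta$spacing_um
  } else {
    stop("voxel spacing unknown: no metadata sidecar found for ", path,
         "; pass spacing = c(dz, dy, dx)")
  }
  if (!is.null(meta)) {
    chn <- meta$channels
    nz <- meta$dim[1]
  } else {
    chn <- if (is.null(channel_names)) "ch1" else channel_names
    if (length(frames) %% length(chn) != 0L)
      stop("frame count is not a multiple of the channel count")
    nz <- length(frames) %/% length(chn)
  }
  ny <- nrow(frames[[1]]); nx <- ncol(frames[[1]])
  channels <- list()
  i <- 0L
  for (nm in chn) {
    arr <- array(0L, dim = c(nz, ny, nx))
    for (z in seq_len(nz)) {
      i <- i + 1L
      arr[z, , ] <- as.integer(round(frames[[i]] * 255))
    }
    channels[[nm]] <- arr
  }
  image_stack(channels, spacing)
}
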