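# Synthetic confocal-like 3D-FISH stacks of sperm nuclei with known ground
# truth. The generator emulates the statistical structure the measurement
# pipeline assumes: a paddle-shaped (flattened-ellipsoid) DNA-counterstained
# nucleus, point-like telomere/centromere signals grouped into clusters,
# diffuse chromosome-territory (CT) blobs, and a configurable fraction of
# nuclei carrying the 13;17 centromeric fusion.

#' Generator parameters and study conditions
#'
#' Returns the default synthetic-data conditions; any element can be
#' overridden by name. Defaults encode the study conditions: acquisition
#' spacing 0.093 x 0.093 x 0.244 um at 8 bits; nucleus semi-axes
#' (6.0, 3.5, 1.5) um (12 um antero-posterior axis, ~3 um depth; the
#' lateral semi-axis is not reported and defaults to 3.5 um); background 10
#' with Gaussian read noise (sd 3) plus Poisson shot noise on signal; spot
#' amplitude 150 (SNR well above 10); anisotropic PSF sigma_xy 0.12 /
#' sigma_z 0.35 um; telomere cluster sizes drawn from {2,3,4} with weights
#' {0.35, 0.40, 0.25} and any remainder as one smaller cluster; chromocenter
#' count distributions matching the reported means (AC6 1.7 control / 1.48
#' fused, SSCRS2A 5.9); pair-category probabilities (0.16, 0.32, 0.52) for
#' control nuclei and (0.32, 0.68, 0) for the fused pair, so that a 50%
#' carrier population reproduces the observed carrier mixture; CT axis
#' positions drawn from truncated normals (sd 15 points) around the
#' reported means.
#'
#' @param ... name = value overrides of any default.
#' @return a `sim_params` list.
#' @export
sim_params <- function(...) {
  p <- list(
    spacing = default_spacing(),
    semi_axes = c(ap = 6.0, lateral = 3.5, depth = 1.5),
    margin = 1.0,                  # um of empty stack around the nucleus
    background = 10,
    read_noise_sd = 3,
    nucleus_intensity = 140,
    amplitude = 150,               # spot peak over background
    ct_amplitude = 150,            # CT plateau over background
    psf_sigma_xy = 0.12,
    psf_sigma_z = 0.35,
    cluster_radius = 0.15,         # member jitter radius within a cluster, um
    min_separation = 1.0,          # min in-plane distance between clusters, um
    cross_channel_clearance = 0.8, # non-associated AC6 vs RS2A clusters, um
    assoc_offset = 0.08,           # centre offset of an associated pair, um
    placement_threshold = 80,      # global threshold placement reasons about
    telomere_cluster_weights = c(`2` = 0.35, `3` = 0.40, `4` = 0.25),
    ac6_cluster_probs = list(control = c(`1` = 0.40, `2` = 0.50, `3` = 0.10),
                             fused   = c(`1` = 0.55, `2` = 0.42, `3` = 0.03)),
    rs2a_cluster_probs = c(`3` = 0.05, `4` = 0.07, `5` = 0.26, `6` = 0.30,
                           `7` = 0.24, `8` = 0.05, `9` = 0.03),
    assoc_probs = list(control = c(`0` = 0.60, `1` = 0.31, `2` = 0.09),
                       fused   = c(`0` = 0.70, `1` = 0.26, `2` = 0.04)),
    pair_category_probs = list(
      control = c(colocalized = 0.16, adjacent = 0.32, distant = 0.52),
      fused   = c(colocalized = 0.32, adjacent = 0.68, distant = 0)),
    ct_volume = c(ssc13 = 4, ssc17 = 3, X = 4, Y = 2),  # um^3
    ct_ap_mean = 50, ct_ap_sd = 20,
    # centre-ML design means: SSC13 peripheral (as high as a territory of
    # its size can sit in the flat nucleus), SSC17 intermediate
    ct_ml_mean = c(ssc13 = 66, ssc17 = 43), ct_ml_sd = 15,
    # ML anchors of proximal pairs: control pairs sit between the two
    # single-territory means; the fused pair is displaced to the central
    # region (the carrier phenotype)
    control_pair_ml_mean = 58,
    fused_pair_ml_mean = 32,
    p_elongated = list(control = c(ssc13 = 0.65, ssc17 = 0.35),
                       fused   = c(ssc13 = 0.40, ssc17 = 0.30)),
    elongated_ratio_range = c(2.2, 3.2),
    round_ratio_range = c(1.0, 1.25),
    gono_ap_mean = c(X = 53, Y = 59),
    gono_ml_mean = c(X = 36.7, Y = 26.7),
    gono_sd = 15,
    ap_range = c(8, 92),           # spot-cluster AP placement band, %
    ml_max = 80,                   # spot-cluster ML placement cap, %
    ct_z_cap = 1.1,                # CT depth semi-axis cap, um
    pair_contact_gap_px = 1.0,     # designed surface gap of adjacent pairs
    pair_overlap_frac = 0.5        # interpenetration of colocalized pairs
  )
  override <- list(...)
  if (length(override)) {
    unknown <- setdiff(names(override), names(p))
    if (length(unknown)) stop("unknown sim_params: ", paste(unknown, collapse = ", "))
    p <- modifyList(p, override)
  }
  structure(p, class = "sim_params")
}

#' Nucleus geometry specification
#'
#' @param semi_axes `c(ap, lateral, depth)` semi-axes in um with
#'   `ap >= lateral >= depth > 0`.
#' @param theta in-plane angle (radians) of the antero-posterior axis.
#' @param anterior_sign +1 or -1: which end of the axis is anterior.
#' @return a `nucleus_spec`.
#' @export
nucleus_spec <- function(semi_axes = c(ap = 6.0, lateral = 3.5, depth = 1.5),
                         theta = 0, anterior_sign = 1L) {
  semi_axes <- as.numeric(semi_axes)
  names(semi_axes) <- c("ap", "lateral", "depth")
  if (any(!is.finite(semi_axes)) || any(semi_axes <= 0) ||
      semi_axes[1] < semi_axes[2] || semi_axes[2] < semi_axes[3])
    stop("semi_axes must satisfy ap >= lateral >= depth > 0")
  if (!anterior_sign %in% c(-1, 1)) stop("anterior_sign must be +1 or -1")
  structure(list(semi_axes = semi_axes, theta = theta,
                 anterior_sign = as.integer(anterior_sign)),
            class = "nucleus_spec")
}

# Stack geometry: dims, nucleus centre and the orthonormal nucleus frame
# (e1 anterior, e2 in-plane perpendicular, e3 optical axis).
.stack_geometry <- function(spec, params, dims = NULL) {
  a <- spec$semi_axes[1]; b <- spec$semi_axes[2]; c3 <- spec$semi_axes[3]
  th <- spec$theta
  sp <- params$spacing
  hx <- sqrt((a * cos(th))^2 + (b * sin(th))^2) + params$margin
  hy <- sqrt((a * sin(th))^2 + (b * cos(th))^2) + params$margin
  hz <- c3 + params$margin
  need <- c(nz = 2L * as.integer(ceiling(hz / sp["dz"])) + 1L,
            ny = 2L * as.integer(ceiling(hy / sp["dy"])) + 1L,
            nx = 2L * as.integer(ceiling(hx / sp["dx"])) + 1L)
  if (is.null(dims)) {
    dims <- need
  } else {
    dims <- as.integer(dims)
    if (any(dims < need))
      stop("nucleus exceeds stack bounds: need at least (",
           paste(need, collapse = ", "), ") voxels (z, y, x)")
  }
  centre <- c(x = (dims[3] - 1) / 2 * sp["dx"],
              y = (dims[2] - 1) / 2 * sp["dy"],
              z = (dims[1] - 1) / 2 * sp["dz"])
  e1 <- spec$anterior_sign * c(cos(th), sin(th), 0)
  e2 <- c(-sin(th), cos(th), 0)
  e3 <- c(0, 0, 1)
  list(dims = unname(dims), spacing = sp, centre = unname(centre),
       e1 = e1, e2 = e2, e3 = e3,
       a = unname(a), b = unname(b), c3 = unname(c3), spec = spec)
}

# Nucleus-frame (t, m, w) -> physical (x, y, z).
.frame_to_xyz <- function(geom, t, m, w = 0) {
  cbind(geom$centre[1] + t * geom$e1[1] + m * geom$e2[1],
        geom$centre[2] + t * geom$e1[2] + m * geom$e2[2],
        geom$centre[3] + w)
}

# Cross-section scale factor of the ellipsoid at axial offset t.
.cs_scale <- function(t, a) sqrt(pmax(0, 1 - (t / a)^2))

# (ap%, ml%, azimuth) -> nucleus-frame (t, m, w).
.apml_to_frame <- function(ap, ml, az, geom) {
  t <- (ap / 50 - 1) * geom$a
  s <- .cs_scale(t, geom$a)
  m <- (ml / 100) * s * geom$b * cos(az)
  w <- (ml / 100) * s * geom$c3 * sin(az)
  cbind(t = t, m = m, w = w)
}

# nucleus-frame -> (ap%, ml%): ml is the fraction of the ray from the axis
# to the analytic ellipsoid border passing through the point.
.frame_to_apml <- function(t, m, w, geom) {
  ap <- 50 * (1 + t / geom$a)
  s <- .cs_scale(t, geom$a)
  ml <- ifelse(s > 0,
               100 * sqrt((m / (s * geom$b))^2 + (w / (s * geom$c3))^2),
               0)
  cbind(ap = ap, ml = ml)
}

# Truncated-normal draw by quantile inversion (deterministic, one uniform
# per value).
.rtnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm((lo - mean) / sd); phi <- pnorm((hi - mean) / sd)
  mean + sd * qnorm(runif(n, plo, phi))
}

# Physical coordinate arrays of a stack grid, dim (nz, ny, nx).
.coord_arrays <- function(dims, sp) {
  list(z = (slice.index(array(0L, dims), 1) - 1) * sp["dz"],
       y = (slice.index(array(0L, dims), 2) - 1) * sp["dy"],
       x = (slice.index(array(0L, dims), 3) - 1) * sp["dx"])
}

#' Render the nucleus counterstain
#'
#' Renders a flattened-ellipsoid nucleus into a voxel grid: a binary region
#' plus a DNA-counterstain intensity channel (noise-free signal; noise is
#' added when the full stack is assembled). The physical extents of the
#' region match twice the semi-axes to within a voxel per axis.
#'
#' @param spec a [nucleus_spec()].
#' @param params a [sim_params()].
#' @param dims optional stack dimensions `(nz, ny, nx)`; an error is raised
#'   if the nucleus does not fit. Default: fitted around the nucleus with
#'   `params$margin` um of clearance.
#' @return list with `mask` (logical array), `signal` (double array, the
#'   noise-free counterstain above background) and `geom` (stack geometry).
#' @export
render_nucleus <- function(spec, params = sim_params(), dims = NULL) {
  stopifnot(inherits(spec, "nucleus_spec"))
  geom <- .stack_geometry(spec, params, dims)
  co <- .coord_arrays(geom$dims, geom$spacing)
  rx <- co$x - geom$centre[1]; ry <- co$y - geom$centre[2]
  rz <- co$z - geom$centre[3]
  t <- rx * geom$e1[1] + ry * geom$e1[2]
  m <- rx * geom$e2[1] + ry * geom$e2[2]
  q2 <- (t / geom$a)^2 + (m / geom$b)^2 + (rz / geom$c3)^2
  mask <- q2 <= 1
  list(mask = mask, signal = params$nucleus_intensity * mask, geom = geom)
}

#' Render point-like FISH spot clusters
#'
#' Each cluster is rendered as `member_count` anisotropic Gaussian spots
#' whose centres are jittered within `params$cluster_radius` of the cluster
#' centre (so members merge into a single above-threshold component), added
#' onto a zero signal channel. Member jitter consumes random numbers from
#' the current RNG stream.
#'
#' @param clusters data frame with columns `member_count`, `ap_percent`,
#'   `ml_percent`, `azimuth` (cluster centres in nucleus coordinates).
#' @param nucleus output of [render_nucleus()] (provides mask + geometry).
#' @param params a [sim_params()].
#' @return double array: the noise-free signal channel.
#' @export
render_spots <- function(clusters, nucleus, params = sim_params()) {
  geom <- nucleus$geom
  sig <- array(0, dim = geom$dims)
  if (is.null(clusters) || nrow(clusters) == 0L) return(sig)
  tmw <- .apml_to_frame(clusters$ap_percent, clusters$ml_percent,
                        clusters$azimuth, geom)
  xyz <- .frame_to_xyz(geom, tmw[, "t"], tmw[, "m"], tmw[, "w"])
  # precondition: cluster centres inside the nucleus region
  q2 <- ((tmw[, "t"]) / geom$a)^2 + ((tmw[, "m"]) / geom$b)^2 +
    ((tmw[, "w"]) / geom$c3)^2
  if (any(q2 > 1 + 1e-9)) stop("cluster centre outside the nucleus")
  for (i in seq_len(nrow(clusters))) {
    k <- clusters$member_count[i]
    ang <- runif(k, 0, 2 * pi)
    rad <- params$cluster_radius * sqrt(runif(k))
    dz <- runif(k, -0.5, 0.5) * params$cluster_radius
    for (j in seq_len(k)) {
      sig <- .add_gaussian_spot(sig, geom,
                                centre = c(xyz[i, 1] + rad[j] * cos(ang[j]),
                                           xyz[i, 2] + rad[j] * sin(ang[j]),
                                           xyz[i, 3] + dz[j]),
                                amplitude = params$amplitude,
                                sxy = params$psf_sigma_xy,
                                sz = params$psf_sigma_z)
    }
  }
  sig
}

# Add one separable anisotropic Gaussian into the signal array (window of
# +/- 4 sigma around the centre).
.add_gaussian_spot <- function(sig, geom, centre, amplitude, sxy, sz) {
  sp <- geom$spacing; d <- geom$dims
  iz <- centre[3] / sp["dz"] + 1; iy <- centre[2] / sp["dy"] + 1
  ix <- centre[1] / sp["dx"] + 1
  wz <- ceiling(4 * sz / sp["dz"]); wxy <- ceiling(4 * sxy / sp["dx"])
  zr <- max(1, floor(iz - wz)):min(d[1], ceiling(iz + wz))
  yr <- max(1, floor(iy - wxy)):min(d[2], ceiling(iy + wxy))
  xr <- max(1, floor(ix - wxy)):min(d[3], ceiling(ix + wxy))
  if (!length(zr) || !length(yr) || !length(xr)) return(sig)
  gz <- exp(-0.5 * (((zr - 1) * sp["dz"] - centre[3]) / sz)^2)
  gy <- exp(-0.5 * (((yr - 1) * sp["dy"] - centre[2]) / sxy)^2)
  gx <- exp(-0.5 * (((xr - 1) * sp["dx"] - centre[1]) / sxy)^2)
  sig[zr, yr, xr] <- sig[zr, yr, xr] + amplitude * (gz %o% gy %o% gx)
  sig
}

#' Chromosome-territory specification
#'
#' @param chromosome name (e.g. `"ssc13"`).
#' @param ap_percent,ml_percent centre position in nucleus coordinates; the
#'   CT centre lies in the nuclear mid-plane.
#' @param side +1/-1, which lateral side of the antero-posterior axis.
#' @param shape `"round"` or `"elongated"`.
#' @param elongation_ratio long/short in-plane axis ratio (>= 1).
#' @param volume_um3 design volume of the half-maximum iso-surface.
#' @param phi in-plane angle of the CT long axis relative to the
#'   antero-posterior axis.
#' @return a `ct_spec` list.
#' @export
ct_spec <- function(chromosome, ap_percent, ml_percent, side = 1,
                    shape = c("round", "elongated"), elongation_ratio = 1,
                    volume_um3 = 4, phi = 0) {
  shape <- match.arg(shape)
  stopifnot(elongation_ratio >= 1, volume_um3 > 0,
            ap_percent >= 0, ap_percent <= 100,
            ml_percent >= 0, ml_percent <= 100)
  structure(list(chromosome = chromosome, ap_percent = ap_percent,
                 ml_percent = ml_percent, side = sign(side),
                 shape = shape, elongation_ratio = elongation_ratio,
                 volume_um3 = volume_um3, phi = phi),
            class = "ct_spec")
}

# Semi-axes (long in-plane, short in-plane, axial) of a CT blob whose
# half-maximum iso-surface has the requested volume; the axial semi-axis is
# capped so the blob fits the flat nucleus.
.ct_semi_axes <- function(volume, ratio, z_cap) {
  s <- (3 * volume / (4 * pi * ratio))^(1 / 3)
  sz <- min(s, z_cap)
  if (sz < s) s <- sqrt(3 * volume / (4 * pi * ratio * sz))
  c(la = ratio * s, sb = s, sc = sz)
}

# In-plane radius of a CT blob along direction alpha (relative to e1), given
# the long-axis direction phi.
.ct_radius <- function(alpha, phi, la, sb) {
  1 / sqrt((cos(alpha - phi) / la)^2 + (sin(alpha - phi) / sb)^2)
}

# In-plane support function of a CT blob: the extent of the ellipse toward a
# separating plane perpendicular to alpha. Two blobs whose centres are
# h1 + h2 + g apart along alpha are separated by a slab of thickness >= g.
.ct_support <- function(alpha, phi, la, sb) {
  sqrt((la * cos(alpha - phi))^2 + (sb * sin(alpha - phi))^2)
}

# Effective radius scale of the segmented blob at the reference threshold:
# the super-Gaussian profile A * 2^(-q^4) crosses (thr - background) at
# q_eff, slightly above 1 for a mid-way threshold.
.ct_q_eff <- function(params) {
  lvl <- (params$placement_threshold - params$background) / params$ct_amplitude
  (log2(1 / lvl))^(1 / 4)
}

#' Render a chromosome-territory blob
#'
#' A diffuse anisotropic blob with a super-Gaussian radial profile
#' `A * 2^(-q^4)` (q = normalized ellipsoidal radius), whose half-maximum
#' iso-surface is the design ellipsoid: thresholding midway between
#' background and plateau recovers an object with the design volume and
#' principal-axis ratio. Raises an error if the blob does not fit inside
#' the nucleus.
#'
#' @param ct a [ct_spec()].
#' @param nucleus output of [render_nucleus()].
#' @param params a [sim_params()].
#' @return double array: the noise-free signal channel contribution.
#' @export
render_ct <- function(ct, nucleus, params = sim_params()) {
  stopifnot(inherits(ct, "ct_spec"))
  geom <- nucleus$geom
  ax <- .ct_semi_axes(ct$volume_um3, ct$elongation_ratio, params$ct_z_cap)
  t <- (ct$ap_percent / 50 - 1) * geom$a
  s <- .cs_scale(t, geom$a)
  m <- ct$side * (ct$ml_percent / 100) * s * geom$b
  if (!.ct_fits(t, m, ct$phi, ax, geom))
    stop("chromosome territory does not fit inside the nucleus")
  .add_ct_blob(array(0, dim = geom$dims), geom, t, m, ct$phi, ax,
               params$ct_amplitude)
}

# Containment: boundary samples of the blob (scaled slightly beyond the
# half-max surface) must stay inside the nucleus ellipsoid.
.ct_fits <- function(t0, m0, phi, ax, geom, scale = 1.1) {
  alphas <- seq(0, 2 * pi, length.out = 9L)[-9L]
  r <- scale * .ct_radius(alphas, phi, ax["la"], ax["sb"])
  tt <- t0 + r * cos(alphas); mm <- m0 + r * sin(alphas)
  q2 <- (tt / geom$a)^2 + (mm / geom$b)^2
  if (any(q2 > 0.97)) return(FALSE)
  # axial extremes at the blob centre
  q2z <- (t0 / geom$a)^2 + (m0 / geom$b)^2 + (scale * ax["sc"] / geom$c3)^2
  q2z <= 0.97
}

.add_ct_blob <- function(sig, geom, t0, m0, phi, ax, amplitude) {
  sp <- geom$spacing; d <- geom$dims
  u1 <- cos(phi) * geom$e1 + sin(phi) * geom$e2
  u2 <- -sin(phi) * geom$e1 + cos(phi) * geom$e2
  ctr <- drop(.frame_to_xyz(geom, t0, m0, 0))
  ext <- 1.6  # render out to q = 1.6 (residual < 2 intensity units)
  hx <- ext * sqrt((ax["la"] * u1[1])^2 + (ax["sb"] * u2[1])^2)
  hy <- ext * sqrt((ax["la"] * u1[2])^2 + (ax["sb"] * u2[2])^2)
  hz <- ext * ax["sc"]
  zr <- max(1, floor((ctr[3] - hz) / sp["dz"] + 1)):min(d[1], ceiling((ctr[3] + hz) / sp["dz"] + 1))
  yr <- max(1, floor((ctr[2] - hy) / sp["dy"] + 1)):min(d[2], ceiling((ctr[2] + hy) / sp["dy"] + 1))
  xr <- max(1, floor((ctr[1] - hx) / sp["dx"] + 1)):min(d[3], ceiling((ctr[1] + hx) / sp["dx"] + 1))
  dz <- (zr - 1) * sp["dz"] - ctr[3]
  dy <- (yr - 1) * sp["dy"] - ctr[2]
  dx <- (xr - 1) * sp["dx"] - ctr[1]
  nzw <- length(zr); nyw <- length(yr); nxw <- length(xr)
  DX <- array(rep(dx, each = nzw * nyw), dim = c(nzw, nyw, nxw))
  DY <- array(rep(rep(dy, each = nzw), times = nxw), dim = c(nzw, nyw, nxw))
  DZ <- array(rep(dz, times = nyw * nxw), dim = c(nzw, nyw, nxw))
  tq <- DX * u1[1] + DY * u1[2]
  mq <- DX * u2[1] + DY * u2[2]
  q2 <- (tq / ax["la"])^2 + (mq / ax["sb"])^2 + (DZ / ax["sc"])^2
  sig[zr, yr, xr] <- sig[zr, yr, xr] + amplitude * 2^(-(q2^2))
  sig
}
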