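# Small in-code fixtures shared across test files.

# Build a segmented_object directly from a voxel index matrix (z, y, x).
make_object <- function(voxels, dims = c(5L, 20L, 20L),
                        spacing = default_spacing(), label = 1L,
                        channel = "toy") {
  spermfish3d:::.new_segmented_object(label, channel, rbind(voxels), dims,
                                      spacing)
}

# A horizontal run of voxels in one z plane: convenient toy objects.
run_voxels <- function(x_from, x_to, y = 5L, z = 3L) {
  cbind(z = z, y = y, x = x_from:x_to)
}

# Render a noise-free nucleus and wrap it as a segmented nucleus object
# (mask attached), bypassing thresholding.
analytic_nucleus <- function(theta = 0, anterior_sign = 1L,
                             params = sim_params(),
                             semi_axes = c(ap = 6, lateral = 3.5, depth = 1.5)) {
  spec <- nucleus_spec(semi_axes, theta = theta, anterior_sign = anterior_sign)
  r <- render_nucleus(spec, params)
  vox <- arrayInd(which(r$mask), dim(r$mask))
  obj <- spermfish3d:::.new_segmented_object(1L, "dna", vox, dim(r$mask),
                                             params$spacing)
  obj$mask <- r$mask
  list(obj = obj, geom = r$geom, render = r)
}

# A small complete synthetic stack: nucleus + a few spot clusters + two CT
# blobs, with noise; used by segmentation and measurement tests.
demo_stack <- function(seed = 123, carrier_fraction = 0, n = 1) {
  pop <- generate_population(n, carrier_fraction, seed = seed)
  list(pop = pop,
       stack = simulate_nucleus(pop$manifest[[1]], pop$params),
       manifest = pop$manifest[[1]])
}

anterior_hint_of <- function(m) {
  m$anterior_sign * c(cos(m$theta), sin(m$theta), 0)
}
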