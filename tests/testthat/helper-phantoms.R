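# shared phantom fixtures, built once per session and cached by key
.phantom_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .phantom_cache)) {
    assign(key, force(expr), envir = .phantom_cache)
  }
  get(key, envir = .phantom_cache)
}

# small unilateral phantom, identity misalignment: fast component tests
ph_identity_uni <- function() {
  cached("identity_uni", generate_phantom(phantom_spec(
    skull_outer_radius = 66, axis_ratios = c(1, 1.2, 0.88),
    aperture_location = "unilateral", aperture_height = 70,
    aperture_width = 70, bulge_height = 25, noise_sd = 0,
    voxel_spacing = c(2, 2, 2.5), seed = 7)))
}

# same geometry, bifrontal aperture
ph_identity_bif <- function() {
  cached("identity_bif", generate_phantom(phantom_spec(
    skull_outer_radius = 66, axis_ratios = c(1, 1.2, 0.88),
    aperture_location = "bifrontal", aperture_height = 70,
    aperture_width = 70, bulge_height = 25, noise_sd = 0,
    voxel_spacing = c(2, 2, 2.5), seed = 7)))
}

# masks derived from the identity unilateral phantom
ph_masks_uni <- function() {
  cached("masks_uni", {
    ph <- ph_identity_uni()
    pre_sk <- skull_mask(ph$pre)
    post_sk <- skull_mask(ph$post)
    list(ph = ph,
         pre_skull = pre_sk, post_skull = post_sk,
         pre_brain = brain_from_inner_table(pre_sk),
         post_brain = segment_brain(ph$post))
  })
}

ph_masks_bif <- function() {
  cached("masks_bif", {
    ph <- ph_identity_bif()
    pre_sk <- skull_mask(ph$pre)
    post_sk <- skull_mask(ph$post)
    list(ph = ph,
         pre_skull = pre_sk, post_skull = post_sk,
         pre_brain = brain_from_inner_table(pre_sk),
         post_brain = segment_brain(ph$post))
  })
}

# component-path deformation summary without registration (identity
# misalignment phantoms share a grid)
measure_identity <- function(m) {
  baseline <- locate_baseline(m$pre_skull, m$post_skull)
  pre_edges <- extract_edge(m$pre_brain)
  post_edges <- extract_edge(m$post_brain)
  field <- displacement_field(pre_edges, post_edges, baseline)
  list(baseline = baseline,
       field = field,
       y_flint = as.numeric(flint_displacement(post_edges, baseline)),
       dV = as.numeric(herniated_volume(m$pre_brain, m$post_brain)))
}
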