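# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# a small deformed cohort for cross-module tests
small_cohort <- function() {
  memo("small_cohort", function() {
    generate_cohort(example_artery_specs(),
                    cohort_config(5, grid_shape = c(64, 64, 64),
                                  seed = 310))
  })
}

# single straight tube phantom, no deformation or noise
tube_template <- function() {
  memo("tube_template", function() {
    specs <- list(artery_spec("tube", rbind(c(5, 5, 2), c(5, 5, 23)),
                              radius_mm = 1.4))
    cfg <- cohort_config(1, grid_shape = c(16, 16, 40),
                         voxel_size_mm = 0.7, deform_amplitude_mm = 0,
                         rigid_rot_deg = 0, rigid_trans_mm = 0,
                         noise_sd = 0)
    list(specs = specs, config = cfg,
         template = render_template(specs, cfg))
  })
}

default_criteria <- function() {
  list(ica_left = segment_criterion("ica_left", 10),
       ica_right = segment_criterion("ica_right", 10),
       basilar = segment_criterion("basilar", 8),
       mca_left = segment_criterion("mca_left", 6),
       mca_right = segment_criterion("mca_right", 6),
       aca = segment_criterion("aca", 8),
       pcoa_left = segment_criterion("pcoa_left", 5))
}

# binary mask helpers
as_mask <- function(arr, voxel = 1) binary_volume(arr, voxel)

solid_cylinder <- function(dim3, centre_xy, radius_vox, z_range) {
  m <- array(FALSE, dim3)
  for (z in z_range)
    for (x in seq_len(dim3[1])) for (y in seq_len(dim3[2]))
      if ((x - centre_xy[1])^2 + (y - centre_xy[2])^2 <= radius_vox^2)
        m[x, y, z] <- TRUE
  m
}
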