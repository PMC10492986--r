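# shared fixtures: small, fast phantom/waveform/cohort specs

tiny_phantom_spec <- function(...) {
  phantom_spec(slice_count = 1L, image_size = 96L, voxel_dims = c(4, 4, 10),
               outer_semiaxes = c(150, 110), sat_thickness = 28,
               vat_blobs = list(list(center = c(25, 0), radius = 22,
                                     fat_fraction = 0.8)), ...)
}

annulus_spec <- function(...) {
  # circular body, uniform ring, no blobs: the analytic-annulus oracle case
  phantom_spec(slice_count = 1L, image_size = 128L, voxel_dims = c(3, 3, 10),
               outer_semiaxes = c(150, 150), sat_thickness = 30, ...)
}

null_cohort_spec <- function(n = 200L, seed = 1L) {
  eff <- default_effects()
  eff[] <- 0
  cohort_spec(n = n, effects = eff, seed = seed)
}
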