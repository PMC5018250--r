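# Shared fixtures, built once per test run. Sizes are kept small: geometry
# checks use a 48-px box at 2.5 A/px, reconstruction checks a 96-px box at
# 2.0 A/px (the package's default desk-scale geometry).

fx_sym <- helical_symmetry(28.2, 12.1, 5)
fx_template <- make_test_subunit(7, width_A = 2.5)

fx_vol48 <- render_volume(fx_template, fx_sym,
                          n_layers = ceiling(48 * 2.5 / 12.1) + 4,
                          box_px = 48, voxel_A = 2.5, clip_z = TRUE)
fx_vol96 <- render_volume(fx_template, fx_sym,
                          n_layers = ceiling(96 * 2.0 / 12.1) + 4,
                          box_px = 96, voxel_A = 2.0, clip_z = TRUE)

fx_pilin <- make_test_pilin(1)
# 10 units per strand: interior units 4-7 are fully coordinated
fx_filament <- suppressWarnings(build_filament_model(fx_pilin, fx_sym, 10))

# rotate a volume about z (resampling)
rotate_volume_z <- function(vol, phi_deg) {
  d <- dim(vol$data)
  out <- helifil:::cpp_affine_sample(as.numeric(vol$data), d,
                                     helifil:::rot_z(-phi_deg), c(0, 0, 0))
  density_volume(array(out, d), vol$voxel_A)
}
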