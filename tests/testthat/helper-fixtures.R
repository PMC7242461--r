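# Shared fixtures: small phantoms and series built in code.

small_config <- function(joint = "joint_space_control", depot = NULL, ...) {
  phantom_config(grid_size = c(64L, 64L), joint_space_tissue = joint,
                 spio_depot = depot, ...)
}

depot_spec <- function(concentration = 1, susceptibility_ppm = 10,
                       radius_mm = 2.8) {
  list(concentration = concentration, susceptibility_ppm = susceptibility_ppm,
       radius_mm = radius_mm)
}

noiseless_series <- function(joint = "joint_space_control",
                             protocol = protocol_preset("cones_ute"), ...) {
  ph <- generate_phantom(small_config(joint = joint, ...), seed = 1)
  list(phantom = ph, series = simulate_series(ph, protocol))
}
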