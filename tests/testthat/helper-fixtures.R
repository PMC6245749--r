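# Shared fixtures, built once per test run.  Trees and waveforms are cheap;
# scenario-scale Monte-Carlo objects are built lazily by the tests that need
# them.

adult_tree <- build_adult_tree()
tree5 <- airway_tree(5)
tree10 <- airway_tree(10)

dpi5 <- maneuver_params(5, "DPI")
neb5 <- maneuver_params(5, "NEBULIZER")

profile_dpi5 <- dpi_profile(dpi5)
profile_neb5 <- nebulizer_profile(neb5)

flow_dpi5 <- distribute_flow(tree5, profile_dpi5)

all_ages <- c(5, 10, 25)
all_contexts <- function(device) {
  stats::setNames(lapply(all_ages, stokes_context_for, device = device),
                  as.character(all_ages))
}

# small deterministic single-row "segment" for closure tests
fake_segment <- function(diameter_m, length_m = 0.02,
                         branching_angle_rad = 0.611,
                         gravity_angle_rad = 0) {
  data.frame(diameter_m = diameter_m, length_m = length_m,
             branching_angle_rad = branching_angle_rad,
             gravity_angle_rad = gravity_angle_rad)
}
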