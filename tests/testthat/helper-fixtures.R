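# Shared fixtures for the test suite. Everything is built in code; the only
# file fixture is the bundled material table.

test_materials <- function() fixture_materials()

# Noiseless punch report sampled from a velocity profile.
sample_profile_report <- function(profile, sampling_rate = 2000,
                                  metadata = list()) {
  time <- seq(0, profile$duration, by = 1 / sampling_rate)
  punch_report(time,
               displacement = profile_displacement(profile, time),
               velocity = profile_velocity(profile, time),
               sampling_rate = sampling_rate, metadata = metadata)
}

# Default rotary-press spec for a material/cam/turret combination.
rotary_spec <- function(material, cam_kind = "conventional",
                        turret_speed = 60, ...) {
  pressure_model_spec(material, fill_cam(cam_kind),
                      machine_config("rotary_press", turret_speed), ...)
}

simulator_spec <- function(material, cam_kind = "conventional",
                           turret_speed = 20, ...) {
  pressure_model_spec(material, fill_cam(cam_kind),
                      machine_config("compaction_simulator", turret_speed),
                      ...)
}
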