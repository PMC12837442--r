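# Shared fixtures for the suite: all built in code at test time.

# clean, strictly periodic steady-state walking (detection studies)
clean_steady <- function(cadence = 1.8, n_steps = 14L, seed = 1L, ...) {
  gait_scenario(n_steps = n_steps, cadence = cadence,
                noise_acc = 0, noise_gyro = 0, noise_yaw_deg = 0,
                seed = seed, startup = FALSE, ...)
}

# clean full trial from standstill (end-to-end studies)
clean_trial <- function(seed = 1L, ...) {
  gait_scenario(noise_acc = 0, noise_gyro = 0, noise_yaw_deg = 0,
                seed = seed, ...)
}

# presets with every noise source switched off
zero_noise_presets <- function() {
  lapply(scenario_presets(), function(sc) {
    sc$noise_acc <- 0; sc$noise_gyro <- 0; sc$noise_yaw_deg <- 0
    sc
  })
}

# presets at the moderate-noise study condition
moderate_noise_presets <- function() {
  lapply(scenario_presets(), function(sc) {
    sc$noise_acc <- 0.15; sc$noise_yaw_deg <- 0.5
    sc
  })
}

# a small recording CSV on disk, returning its path
write_fixture_csv <- function(df, dir = tempdir()) {
  path <- tempfile("rec", tmpdir = dir, fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
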