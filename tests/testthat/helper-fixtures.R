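# Small fixtures built in code.

# static IMU trace: constant accel/gyro vectors
make_static_imu <- function(accel = c(0, 0, 9.81), gyro = c(0, 0, 0),
                            n = 200, rate = 100) {
  t <- (seq_len(n) - 1) / rate
  imu_trace(t, matrix(rep(accel, each = n), n),
            matrix(rep(gyro, each = n), n), rate = rate)
}

# single-axis sinusoidal acceleration on ax, gravity on az
make_sine_imu <- function(amp = 9.81, freq = 1, n = 1000, rate = 100) {
  t <- (seq_len(n) - 1) / rate
  imu_trace(t, cbind(amp * sin(2 * pi * freq * t), 0, 9.81),
            matrix(0, n, 3), rate = rate)
}

# hand-built label series on a uniform grid
make_labels <- function(phases, dt = 0.1, t0 = 0) {
  phase_label_series(t0 + (seq_along(phases) - 1) * dt, phases)
}

quiet_profile <- function(...) subject_profile(noise_sd_accel = 0,
                                               noise_sd_gyro = 0, ...)
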