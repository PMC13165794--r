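# Shared fixtures: a small 3-section course for fast full-chain tests and a
# compact profile constructor.

mini_course <- function() {
  build_course(data.frame(
    index = 1:3,
    start_distance = c(0, 30, 70),
    length = c(30, 40, 30),
    v_mean = c(0.9, 1.4, 1.1),
    v_sd = c(0.20, 0.30, 0.25),
    copx_mean = c(-2, 4, -1),
    copx_sd = c(6, 8, 7),
    copy_mean = c(-18, -22, -19),
    copy_sd = c(8, 9, 8),
    turn_in = c("none", "right", "left"),
    stringsAsFactors = FALSE
  ))
}

prof <- function(id = "P1", lambda = 0.5, scale = 1, offx = 0, ns = 1L) {
  participant_profile(id, lambda, scale, offx, noise_seed = ns)
}

# noise-free simulator settings
quiet_opts <- function(...) {
  sim_options(noise_scale = 0, gps_sigma = 0, ...)
}
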