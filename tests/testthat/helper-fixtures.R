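# Shared fixtures, built once per test run. Small schedules and coarse
# grids keep each fixture in the tens of milliseconds while exercising
# the same code paths as the full-size defaults.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- builder()
  fixture_env[[key]]
}

small_schedule <- function(n = 60) {
  memo(paste0("sched", n), function()
    default_schedule(n_excitations = n, tr = 9.3, te = 2))
}

small_dictionary <- function() {
  memo("dict", function()
    build_dictionary(small_schedule(), t1_values = seq(400, 2000, by = 200),
                     t2_values = seq(40, 200, by = 20)))
}

small_cdict <- function(k = 4) {
  memo(paste0("cdict", k), function()
    compress_dictionary(small_dictionary(), k = k))
}

# coarser grid but the full-length default schedule: used where SV-domain
# discrimination matters (matching under noise, phantom pipeline)
pipeline_cdict <- function() {
  memo("pipeline_cdict", function() {
    g <- default_grid()
    compress_dictionary(
      build_dictionary(default_schedule(),
                       t1_values = g$t1[seq(1, length(g$t1), by = 2)],
                       t2_values = g$t2[seq(1, length(g$t2), by = 2)]),
      k = 4)
  })
}

# independent oracle: step the Bloch recursion one explicit 3-vector /
# 3x3-matrix operation at a time (no vectorization, no shared code path
# with simulate_fingerprints beyond the model definition)
bloch_oracle <- function(schedule, t1, t2, pd = 1, spoil = FALSE) {
  deg2rad <- pi / 180
  rot_z <- function(t) matrix(c(cos(t), sin(t), 0,
                                -sin(t), cos(t), 0,
                                0, 0, 1), 3, 3)
  rot_x <- function(t) matrix(c(1, 0, 0,
                                0, cos(t), sin(t),
                                0, -sin(t), cos(t)), 3, 3)
  M <- c(0, 0, 1)
  if (schedule$invert_first) {
    M <- c(M[1], M[2], -M[3])
    d <- schedule$inversion_delay
    M <- c(M[1] * exp(-d / t2), M[2] * exp(-d / t2),
           1 + (M[3] - 1) * exp(-d / t1))
  }
  out <- complex(length.out = schedule$n_excitations)
  for (i in seq_len(schedule$n_excitations)) {
    a <- schedule$flip_angle[i] * deg2rad
    p <- schedule$rf_phase[i] * deg2rad
    R <- rot_z(p) %*% rot_x(a) %*% rot_z(-p)
    M <- as.vector(R %*% M)
    out[i] <- complex(real = M[1], imaginary = M[2]) *
      exp(-schedule$te[i] / t2)
    e2 <- exp(-schedule$tr[i] / t2)
    e1 <- exp(-schedule$tr[i] / t1)
    M <- c(M[1] * e2, M[2] * e2, 1 + (M[3] - 1) * e1)
    if (spoil) M[1] <- M[2] <- 0
  }
  out * pd
}

# small phantom cohort shared by integration-style tests
tiny_phantom_pair <- function(seed = 42, noise = 0.02) {
  memo(paste0("pair", seed, "_", noise), function()
    generate_pair(phantom_spec(seed = seed, noise_sigma = noise),
                  1, pipeline_cdict()))
}
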