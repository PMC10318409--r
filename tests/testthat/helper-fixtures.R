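# shared fixtures, all built in code

calib_25c <- function() fit_stern_volmer(573, 160, 1.0, 25)
calib_30c <- function() fit_stern_volmer(526, 144, 1.0, 30)

OMEGA <- 2 * pi * 550e3   # default modulation angular frequency (rad/s)

# single-pixel-uniform modulated stack with a chosen mono-exponential lifetime
mono_stack <- function(tau_ns, k = 8, shape = c(4, 4), dc = 1000,
                       f_hz = 550e3) {
  w <- 2 * pi * f_hz
  ph <- atan(w * tau_ns * 1e-9)
  m <- 1 / sqrt(1 + (w * tau_ns * 1e-9)^2)
  series <- dc * (1 + m * cos(2 * pi * (0:(k - 1)) / k - ph))
  modulated_stack(array(rep(series, prod(shape)), dim = c(k, shape)),
                  modulation_frequency_hz = f_hz)
}

# constant-oxygen trace over a duration (h), sampled every 5 min
flat_trace <- function(o2 = 0.21, duration_h = 9, interval_min = 5) {
  times <- seq(0, duration_h * 3600, by = interval_min * 60)
  o2_trace(times, rep(o2, length(times)), source_roi = "fixture")
}

# a small label mask with three rectangular cells; one touches the left edge
three_cell_mask <- function(nr = 40, nc = 60) {
  m <- matrix(0L, nr, nc)
  m[15:20, 1:6] <- 1L      # touches the left image border
  m[12:17, 25:32] <- 2L
  m[22:28, 40:48] <- 3L
  m
}
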