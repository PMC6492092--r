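# Shared fixtures, computed lazily once per test session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, .fixtures)) assign(name, force(expr), .fixtures)
  get(name, .fixtures)
}

tissue_lib <- function() memo("lib", default_tissue_library())

default_signals <- function() {
  memo("signals", tissue_signals(tissue_lib()))
}

# small phantom used by most unit tests (48 x 48 x 24 at 2.8 mm)
small_phantom <- function() {
  memo("small_phantom", suppressWarnings(
    make_phantom(phantom_config(grid = c(48, 48, 24), spacing = 2.8),
                 tissue_lib())))
}

# a full-grid single-beat schedule for Fourier-inversion style tests
full_schedule <- function(grid) {
  full <- expand.grid(ky = wholeheart:::kfreq(grid[2]),
                      kz = wholeheart:::kfreq(grid[3]))
  sch <- data.frame(beat = 1L, parity = "odd", line = seq_len(nrow(full)),
                    ky = full$ky, kz = full$kz)
  attr(sch, "grid") <- c(Nky = grid[2], Nkz = grid[3])
  attr(sch, "golden_angle") <- 137.508
  class(sch) <- c("sampling_schedule", "data.frame")
  sch
}

static_trace <- function(si = 0, rl = 0) {
  data.frame(beat = 1L, time_ms = 0, si = si, rl = rl)
}

uniform_coil <- function(grid) array(1 + 0i, c(grid, 1))

# test image with smooth structure, reproducible
smooth_test_image <- function(grid, seed = 11) {
  set.seed(seed)
  x <- array(stats::rnorm(prod(grid)), grid)
  wholeheart:::gaussian_smooth(x, 1.5)
}
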