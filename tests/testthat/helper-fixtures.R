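# Shared fixtures. Expensive objects (the full default dictionary) are built
# once per test run and memoized.

default_config <- seq_config()
default_profile <- slice_profile()

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# full default dictionary: T1 100..3000 step 5, 581 atoms of length 50
get_dictionary <- function() {
  memo("dict_full", function() build_dictionary(default_config, default_profile))
}

# coarse grid for quick structural tests
get_dictionary_coarse <- function() {
  memo("dict_coarse", function() {
    build_dictionary(default_config, default_profile, t1_step = 50)
  })
}

# Independent closed-form Look-Locker oracle: longitudinal recursion under
# ideal spoiling, written without touching the package EPG engine.
ll_closed_form <- function(t1_ms, t2_ms, flip_deg, config) {
  a <- flip_deg * pi / 180
  E1 <- exp(-config$tr_ms / t1_ms)
  te <- rep(c(config$te1_ms, config$te2_ms), length.out = config$n_excitations)
  mz <- -config$inv_efficiency
  out <- complex(config$n_excitations)
  for (j in seq_len(config$n_excitations)) {
    out[j] <- -1i * mz * sin(a) * exp(-te[j] / t2_ms)
    mz <- 1 + (mz * cos(a) - 1) * E1
  }
  out
}

# Independent isochromat (Bloch) oracle for the gradient-spoiled train:
# uniform intra-voxel dephasing of one cycle per TR, no configuration-state
# bookkeeping.
bloch_gradient_spoiled <- function(t1_ms, t2_ms, flip_deg, config,
                                   n_iso = 400) {
  a <- flip_deg * pi / 180
  phis <- (seq_len(n_iso) - 0.5) / n_iso * 2 * pi
  n <- config$n_excitations
  te <- rep(c(config$te1_ms, config$te2_ms), length.out = n)
  E1 <- exp(-config$tr_ms / t1_ms)
  E2 <- exp(-config$tr_ms / t2_ms)
  M <- matrix(0, 3, n_iso)
  M[3, ] <- -config$inv_efficiency
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  sig <- complex(n)
  for (j in seq_len(n)) {
    M <- Rx %*% M
    sig[j] <- mean(complex(real = M[1, ], imaginary = M[2, ])) *
      exp(-te[j] / t2_ms)
    M[1, ] <- M[1, ] * E2
    M[2, ] <- M[2, ] * E2
    M[3, ] <- M[3, ] * E1 + (1 - E1)
    x <- M[1, ] * cos(phis) - M[2, ] * sin(phis)
    y <- M[1, ] * sin(phis) + M[2, ] * cos(phis)
    M[1, ] <- x
    M[2, ] <- y
  }
  sig
}

# centered Gaussian blob on the reconstruction grid
gaussian_phantom <- function(n, fov_mm, sigma_mm) {
  xy <- (seq_len(n) - 1 - n / 2) * (fov_mm / n)
  exp(-outer(xy^2, xy^2, "+") / (2 * sigma_mm^2))
}

# 12-vial phantom spanning wide wT1 / PDFF ranges for recovery tests
wide_range_spec <- function(wt1 = c(300, 800, 1400, 2000),
                            pdff = c(0, 20, 40), b0 = c(-40, 0, 30),
                            noise_sigma = 0, seed = 1L) {
  phantom_spec(
    matrix_size = 48, fov_mm = 144, noise_sigma = noise_sigma, seed = seed,
    vials = data.frame(
      x_mm = rep(c(-45, -15, 15, 45), 3),
      y_mm = rep(c(-40, 0, 40), each = 4),
      radius_mm = 9,
      wt1_ms = rep(wt1, 3),
      pdff_percent = rep(pdff, each = 4),
      b0_hz = rep(b0, each = 4)))
}
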