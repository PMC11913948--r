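#' Digital vial phantom specification
#'
#' Describes a vial phantom in the style of commercial fat-fraction/T1
#' calibration phantoms: circular vials on a grid, each with its own water
#' T1, proton-density fat fraction and off-resonance. The default layout is
#' 12 vials in 3 rows of constant PDFF (0, 5, 10 percent) by 4 columns of
#' increasing wT1.
#'
#' @param matrix_size Image matrix (square).
#' @param fov_mm In-plane field of view in mm.
#' @param vials Data frame with columns `x_mm`, `y_mm`, `radius_mm`,
#'   `wt1_ms`, `pdff_percent`, `b0_hz`; `NULL` builds the default 12-vial
#'   layout from the row/column arguments.
#' @param wt1_columns_ms wT1 of the four columns (default layout).
#' @param pdff_rows_percent PDFF of the three rows (default layout).
#' @param vial_radius_mm Vial radius (default layout).
#' @param b0_hz Off-resonance applied to every vial (default layout).
#' @param background Background proton density (0 = empty).
#' @param noise_sigma Complex-noise standard deviation for the simulated
#'   series.
#' @param seed Seed fixing all randomness of the simulation.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(matrix_size = 64, fov_mm = 128, vials = NULL,
                         wt1_columns_ms = c(400, 700, 1000, 1300),
                         pdff_rows_percent = c(0, 5, 10),
                         vial_radius_mm = 10, b0_hz = 0,
                         background = 0, noise_sigma = 0, seed = 1L) {
  if (is.null(vials)) {
    ncol_v <- length(wt1_columns_ms)
    nrow_v <- length(pdff_rows_percent)
    xs <- (seq_len(ncol_v) - (ncol_v + 1) / 2) * fov_mm / (ncol_v + 0.5)
    ys <- (seq_len(nrow_v) - (nrow_v + 1) / 2) * fov_mm / (nrow_v + 1)
    vials <- expand.grid(col = seq_len(ncol_v), row = seq_len(nrow_v))
    vials <- data.frame(
      x_mm = xs[vials$col], y_mm = ys[vials$row],
      radius_mm = vial_radius_mm,
      wt1_ms = wt1_columns_ms[vials$col],
      pdff_percent = pdff_rows_percent[vials$row],
      b0_hz = b0_hz
    )
  }
  stopifnot(all(c("x_mm", "y_mm", "radius_mm", "wt1_ms", "pdff_percent",
                  "b0_hz") %in% names(vials)),
            all(vials$pdff_percent >= 0), all(vials$pdff_percent <= 100),
            all(vials$wt1_ms > 0))
  out <- list(matrix_size = as.integer(matrix_size), fov_mm = fov_mm,
              vials = vials, background = background,
              noise_sigma = noise_sigma, seed = as.integer(seed))
  class(out) <- "phantom_spec"
  out
}

#' Rasterize a phantom specification into ground-truth maps
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_truth`: list with matrices `wt1_ms`,
#'   `pdff_percent`, `b0_hz`, `rho` (proton density), a list of per-vial
#'   logical `masks`, the `vials` table and geometry fields.
#' @export
make_vial_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  v <- spec$vials
  nv <- nrow(v)
  if (nv > 1) {
    d <- as.matrix(stats::dist(cbind(v$x_mm, v$y_mm)))
    rr <- outer(v$radius_mm, v$radius_mm, "+")
    if (any(d[upper.tri(d)] < rr[upper.tri(rr)])) stop("overlapping vials")
  }
  n <- spec$matrix_size
  xy <- grid_coords_mm(n, spec$fov_mm)
  X <- matrix(xy, n, n)
  Y <- matrix(xy, n, n, byrow = TRUE)
  wt1 <- matrix(NA_real_, n, n)
  pdff <- matrix(0, n, n)
  b0 <- matrix(0, n, n)
  rho <- matrix(spec$background, n, n)
  masks <- vector("list", nv)
  for (i in seq_len(nv)) {
    m <- if (v$radius_mm[i] > 0) {
      (X - v$x_mm[i])^2 + (Y - v$y_mm[i])^2 <= v$radius_mm[i]^2
    } else matrix(FALSE, n, n)
    masks[[i]] <- m
    wt1[m] <- v$wt1_ms[i]
    pdff[m] <- v$pdff_percent[i]
    b0[m] <- v$b0_hz[i]
    rho[m] <- 1
  }
  out <- list(wt1_ms = wt1, pdff_percent = pdff, b0_hz = b0, rho = rho,
              masks = masks, vials = v,
              matrix_size = n, fov_mm = spec$fov_mm,
              noise_sigma = spec$noise_sigma, seed = spec$seed)
  class(out) <- "phantom_truth"
  out
}

# composite signal train for one tissue: water + multi-peak fat, per TE
composite_signal <- function(wt1_ms, pdff_percent, config, fat_model,
                             fat_t1_ms, fat_t2_ms, water_t2_ms, profile,
                             s_fat = NULL) {
  w <- 1 - pdff_percent / 100
  f <- pdff_percent / 100
  s_w <- simulate_with_profile(wt1_ms, water_t2_ms, config, profile)
  if (is.null(s_fat)) {
    s_fat <- simulate_with_profile(fat_t1_ms, fat_t2_ms, config, profile)
  }
  cf <- fat_phasor(fat_model, te_schedule(config))
  w * s_w + cf * f * s_fat
}

#' Forward-simulate the composite TR series of a phantom
#'
#' Per pixel, the water train is simulated at the pixel wT1 and the fat train
#' at `fat_t1_ms` (both with the dictionary slice profile), combined as
#' `W s_w(n) + c_F(TE_n) F s_f(n)` with W/F set by the PDFF, then the B0
#' phase `exp(i 2 pi b0 TE_n)` is applied. In `k_space` mode each image is
#' additionally sampled along one rotating spiral arm (with off-resonance
#' phase accrual over the readout) and gridded back, emulating the
#' single-shot acquisition; the raw samples are kept in the `kspace`
#' attribute so the deblurring stage can operate on them. Seeded complex
#' Gaussian noise is added last.
#'
#' @param truth A [make_vial_phantom()] result.
#' @param config A [seq_config()].
#' @param fat_model A [fat_model()].
#' @param fat_t1_ms,fat_t2_ms Fat relaxation times in ms.
#' @param water_t2_ms Water T2 used in the forward simulation.
#' @param profile Slice profile used for the simulated trains.
#' @param mode `"image_space"` or `"k_space"`.
#' @param traj Spiral trajectory for `k_space` mode; defaults to
#'   [make_spiral()] on the phantom geometry.
#' @param noise_sigma Complex noise sd; defaults to the phantom spec value.
#' @param seed Seed; defaults to the phantom spec value.
#' @return A [composite_series()]; in `k_space` mode with attribute `kspace`
#'   (list: `samples` matrix, `arm_indices`, `traj`).
#' @export
simulate_composite_series <- function(truth, config = seq_config(),
                                      fat_model = fat_model_7peak(),
                                      fat_t1_ms = 380, fat_t2_ms = 50,
                                      water_t2_ms = 50,
                                      profile = slice_profile(),
                                      mode = c("image_space", "k_space"),
                                      traj = NULL, noise_sigma = NULL,
                                      seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(truth, "phantom_truth"))
  if (is.null(noise_sigma)) noise_sigma <- truth$noise_sigma
  if (is.null(seed)) seed <- truth$seed
  n <- truth$matrix_size
  nex <- config$n_excitations
  te <- te_schedule(config)

  tissue <- data.frame(wt1 = as.vector(truth$wt1_ms),
                       pdff = as.vector(truth$pdff_percent),
                       rho = as.vector(truth$rho))
  key <- paste(tissue$wt1, tissue$pdff)
  active <- tissue$rho != 0 & !is.na(tissue$wt1)
  ukey <- unique(key[active])

  s_fat <- simulate_with_profile(fat_t1_ms, fat_t2_ms, config, profile)
  series <- array(0 + 0i, c(n, n, nex))
  flat <- matrix(series, n * n, nex)
  for (uk in ukey) {
    sel <- active & key == uk
    i0 <- which(sel)[1]
    sig <- composite_signal(tissue$wt1[i0], tissue$pdff[i0], config,
                            fat_model, fat_t1_ms, fat_t2_ms, water_t2_ms,
                            profile, s_fat = s_fat)
    flat[sel, ] <- matrix(sig, nrow = sum(sel), ncol = nex, byrow = TRUE) *
      tissue$rho[sel]
  }
  series <- array(flat, c(n, n, nex))

  if (mode == "image_space") {
    b0ph <- exp(2i * pi * outer(as.vector(truth$b0_hz), te) / 1000)
    series <- array(matrix(series, n * n, nex) * b0ph, c(n, n, nex))
  } else {
    if (is.null(traj)) {
      traj <- make_spiral(truth$fov_mm, n, config$readout_ms)
    }
    arms <- (seq_len(nex) - 1L) %% traj$n_arms_full
    samples <- matrix(0 + 0i, length(traj$arm_k), nex)
    recon <- array(0 + 0i, c(n, n, nex))
    for (j in seq_len(nex)) {
      samples[, j] <- forward_sample(series[, , j], traj, arms[j],
                                     b0map = truth$b0_hz, te_ms = te[j])
      recon[, , j] <- grid_recon(samples[, j], traj, arms[j])
    }
    series <- recon
    kspace <- list(samples = samples, arm_indices = arms, traj = traj)
  }

  if (noise_sigma > 0) {
    set.seed(seed)
    series <- series + complex(
      real = stats::rnorm(length(series), sd = noise_sigma),
      imaginary = stats::rnorm(length(series), sd = noise_sigma))
  }
  out <- composite_series(series, te, truth$fov_mm)
  if (mode == "k_space") attr(out, "kspace") <- kspace
  out
}

#' Fat-bias surface of composite-signal T1
#'
#' For every (wT1, PDFF) combination, simulates the noiseless composite
#' signal train, extracts the TE1-only and TE2-only 50-point series (i.e.
#' skipping the water-fat separation step) and matches each directly to the
#' water dictionary. Returns the percent deviation of the composite T1 from
#' the true water T1 per TE branch.
#'
#' @param wt1_ms,pdff_percent Grid vectors.
#' @param config A [seq_config()].
#' @param fat_model A [fat_model()].
#' @param fat_t1_ms,fat_t2_ms Fat relaxation in ms.
#' @param dictionary Matching dictionary; the default 100-3000 ms grid is
#'   built if omitted.
#' @param profile Slice profile shared by simulation and dictionary.
#' @return Data frame of class `wt1_bias_grid` with columns `wt1_ms`,
#'   `pdff_percent`, `te_branch` (1 or 2), `t1comp_ms`, `deviation_pct`
#'   (= 100 (T1comp - wT1) / wT1).
#' @export
simulate_bias_grid <- function(wt1_ms = seq(600, 1700, by = 100),
                               pdff_percent = seq(5, 40, by = 5),
                               config = seq_config(),
                               fat_model = fat_model_7peak(),
                               fat_t1_ms = 380, fat_t2_ms = 50,
                               dictionary = NULL,
                               profile = slice_profile()) {
  stopifnot(length(wt1_ms) >= 1, length(pdff_percent) >= 1)
  if (is.null(dictionary)) dictionary <- build_dictionary(config, profile)
  s_fat <- simulate_with_profile(fat_t1_ms, fat_t2_ms, config, profile)
  s_w <- simulate_with_profile(wt1_ms, 50, config, profile)
  if (is.null(dim(s_w))) s_w <- matrix(s_w, ncol = 1)
  cf <- fat_phasor(fat_model, te_schedule(config))
  idx1 <- seq.int(1L, config$n_excitations, by = 2L)
  idx2 <- seq.int(2L, config$n_excitations, by = 2L)

  rows <- expand.grid(wt1_ms = wt1_ms, pdff_percent = pdff_percent,
                      te_branch = c(1L, 2L))
  rows$t1comp_ms <- NA_real_
  for (r in seq_len(nrow(rows))) {
    iw <- match(rows$wt1_ms[r], wt1_ms)
    p <- rows$pdff_percent[r]
    sig <- (1 - p / 100) * s_w[, iw] + cf * (p / 100) * s_fat
    branch <- if (rows$te_branch[r] == 1L) sig[idx1] else sig[idx2]
    rows$t1comp_ms[r] <- match_signal(branch, dictionary)$t1_ms
  }
  rows$deviation_pct <- 100 * (rows$t1comp_ms - rows$wt1_ms) / rows$wt1_ms
  class(rows) <- c("wt1_bias_grid", "data.frame")
  rows
}
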