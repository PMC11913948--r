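#' Uniform-density Archimedean spiral trajectory
#'
#' Builds one spiral arm reaching the Nyquist radius `matrix / (2 FOV)`
#' (cycles/mm) at the end of the readout, with radius growing linearly in
#' angle (uniform sampling density). The number of turns is chosen so that
#' `n_arms_full` uniformly rotated copies of the arm satisfy the radial
#' Nyquist criterion (gap between adjacent turns of the full set at most
#' `1/FOV`), and the along-arm sample spacing also respects `1/FOV`.
#' Analytic density compensation weights proportional to `|k|` (annular area
#' per sample) are attached. Hardware slew/amplitude limits are not modeled;
#' this is a simulation trajectory, not a waveform export.
#'
#' @param fov_mm Field of view in mm.
#' @param matrix Matrix size.
#' @param readout_ms Readout duration in ms.
#' @param n_arms_full Number of arms for a fully sampled scan; defaults to
#'   [nyquist_arms()] for 4 spiral turns.
#' @param te_ms Time stamp of the first sample (echo time), in ms.
#' @param oversample Along-arm sampling density relative to the Nyquist
#'   minimum.
#' @return An object of class `spiral_trajectory`: list with complex `arm_k`
#'   (arm 0 coordinates, cycles/mm), `t_ms` (per-sample time stamps starting
#'   at `te_ms`), `dcf`, `n_arms_full`, `rotation_deg_per_tr`, `fov_mm`,
#'   `matrix`, `readout_ms`, `n_turns`.
#' @export
make_spiral <- function(fov_mm, matrix, readout_ms, n_arms_full = NULL,
                        te_ms = 0, oversample = 1.2) {
  stopifnot(matrix >= 16, readout_ms > 0, fov_mm > 0)
  kmax <- matrix / (2 * fov_mm)
  if (is.null(n_arms_full)) n_arms_full <- nyquist_arms(fov_mm, matrix)
  n_arms_full <- as.integer(n_arms_full)
  if (n_arms_full < 1) stop("n_arms_full must be at least 1")
  # radial Nyquist: kmax / (n_turns * n_arms_full) <= 1/FOV
  n_turns <- ceiling(kmax * fov_mm / n_arms_full)

  # choose sample count from the arc length at Nyquist spacing
  arc <- pi * n_turns * kmax  # Archimedean arc length, leading order
  n_samp <- max(64L, ceiling(arc * fov_mm * oversample))
  tau <- seq(0, 1, length.out = n_samp)
  theta <- 2 * pi * n_turns * tau
  arm <- kmax * tau * exp(1i * theta)
  t_ms <- te_ms + tau * readout_ms

  # annular-area weights: dA = |k| dtheta dk_r; center sample gets the disc
  dtheta <- 2 * pi * n_turns / (n_samp - 1)
  dkr <- kmax / (n_turns * n_arms_full)
  dcf <- Mod(arm) * dtheta * dkr
  # every arm starts at exactly k = 0: share the central disc between arms
  dcf[1] <- pi * (dkr / 2)^2 / n_arms_full

  out <- list(
    arm_k = arm, t_ms = t_ms, dcf = dcf,
    n_arms_full = n_arms_full,
    rotation_deg_per_tr = 360 / n_arms_full,
    fov_mm = fov_mm, matrix = as.integer(matrix),
    readout_ms = readout_ms, n_turns = n_turns, te_ms = te_ms
  )
  class(out) <- "spiral_trajectory"
  out
}

#' @export
print.spiral_trajectory <- function(x, ...) {
  cat(sprintf(
    "<spiral_trajectory> %d samples/arm, %d turns, %d full arms (%.2f deg/TR), kmax %.4f /mm\n",
    length(x$arm_k), x$n_turns, x$n_arms_full, x$rotation_deg_per_tr,
    max(Mod(x$arm_k))))
  invisible(x)
}

#' Arms needed for full azimuthal sampling
#'
#' Smallest number of uniformly rotated arms such that, for a spiral of
#' `n_turns` turns, the radial gap between adjacent turns of the full set is
#' at most `1/FOV`.
#'
#' @param fov_mm Field of view in mm.
#' @param matrix Matrix size.
#' @param n_turns Spiral turns per arm.
#' @return Integer arm count.
#' @export
nyquist_arms <- function(fov_mm, matrix, n_turns = 4) {
  kmax <- matrix / (2 * fov_mm)
  as.integer(ceiling(kmax * fov_mm / n_turns))
}

#' K-space coordinates of one rotated arm
#'
#' @param traj A [make_spiral()] trajectory.
#' @param arm_index 0-based arm index; arm `i` is arm 0 rotated by
#'   `i * 360 / n_arms_full` degrees.
#' @return Complex vector of k-space coordinates (cycles/mm).
#' @export
arm_coordinates <- function(traj, arm_index) {
  if (arm_index < 0 || arm_index >= traj$n_arms_full) {
    stop("arm index out of range")
  }
  traj$arm_k * exp(1i * 2 * pi * arm_index / traj$n_arms_full)
}

# pixel center coordinates (mm) of an n x n grid over the FOV
grid_coords_mm <- function(n, fov_mm) {
  (seq_len(n) - 1 - n / 2) * (fov_mm / n)
}

#' Forward spiral sampling of an image with off-resonance
#'
#' Exact non-uniform discrete Fourier transform of the image along one spiral
#' arm, with per-sample off-resonance phase `exp(i 2 pi b0(x) t)` accrued at
#' the sample time stamps (positive off-resonance accrues positive phase,
#' matching the separation module's convention).
#'
#' @param image Complex (or numeric) square matrix.
#' @param traj A [make_spiral()] trajectory.
#' @param arm_index 0-based arm index.
#' @param b0map Off-resonance map in Hz (same shape as `image`), or `NULL`.
#' @param te_ms Optional override of the first-sample time stamp.
#' @return Complex vector, one sample per trajectory point.
#' @export
forward_sample <- function(image, traj, arm_index, b0map = NULL, te_ms = NULL) {
  stopifnot(nrow(image) == ncol(image))
  n <- nrow(image)
  if (!is.null(b0map)) stopifnot(all(dim(b0map) == dim(image)),
                                 all(is.finite(b0map)))
  k <- arm_coordinates(traj, arm_index)
  t_ms <- traj$t_ms
  if (!is.null(te_ms)) t_ms <- te_ms + (traj$t_ms - traj$t_ms[1])
  xy <- grid_coords_mm(n, traj$fov_mm)
  px <- rep(xy, times = n)     # x varies fastest (column-major)
  py <- rep(xy, each = n)
  img <- as.vector(image)
  if (!is.null(b0map)) {
    # phase accrual differs per sample time: loop over samples, vectorized
    # over pixels
    b0 <- as.vector(b0map)
    vapply(seq_along(k), function(j) {
      ph <- exp(-2i * pi * (Re(k[j]) * px + Im(k[j]) * py) +
                  2i * pi * b0 * t_ms[j] / 1000)
      sum(img * ph)
    }, complex(1))
  } else {
    E <- exp(-2i * pi * (outer(px, Re(k)) + outer(py, Im(k))))
    as.vector(crossprod(E, img))
  }
}

#' Reconstruction of spiral samples onto the image grid
#'
#' `method = "adjoint"` (default) is the classical gridding step: the
#' density-compensated adjoint non-uniform Fourier transform. It is fast and
#' mirrors what scanner reconstruction does, but at desk-scale matrix sizes
#' the spiral has only a handful of turns, so the Riemann-sum density
#' weights leave a visible low-frequency quadrature error. `method = "lsq"`
#' solves the (Tikhonov-regularized) least-squares inverse of the same
#' non-uniform Fourier operator by conjugate gradients, which is
#' quantitatively exact on fully sampled noiseless data. Both are linear in
#' the data.
#'
#' @param ksamples Complex vector of samples (concatenated arms).
#' @param traj A [make_spiral()] trajectory.
#' @param arm_indices 0-based arm index per arm of `ksamples`.
#' @param matrix Output matrix size; defaults to the trajectory matrix.
#' @param method `"adjoint"` or `"lsq"`.
#' @param iters,lambda Conjugate-gradient iterations and Tikhonov weight for
#'   `"lsq"`.
#' @return Complex image matrix.
#' @export
grid_recon <- function(ksamples, traj, arm_indices = 0, matrix = NULL,
                       method = c("adjoint", "lsq"), iters = 40,
                       lambda = 1e-6) {
  method <- match.arg(method)
  if (is.null(matrix)) matrix <- traj$matrix
  ns <- length(traj$arm_k)
  if (length(ksamples) != ns * length(arm_indices)) {
    stop("sample count does not match trajectory arms")
  }
  k <- unlist(lapply(arm_indices, function(a) arm_coordinates(traj, a)))
  xy <- grid_coords_mm(matrix, traj$fov_mm)
  px <- rep(xy, times = matrix)
  py <- rep(xy, each = matrix)
  E <- exp(2i * pi * (outer(px, Re(k)) + outer(py, Im(k))))
  if (method == "adjoint") {
    w <- rep(traj$dcf, times = length(arm_indices))
    img <- E %*% (w * ksamples)
    # area-weighted adjoint approximates the inverse FT; the pixel-area
    # factor makes forward-then-adjoint an (approximate) identity
    return(matrix(img * (traj$fov_mm / matrix)^2, matrix, matrix))
  }
  # CG on the normal equations (E E^H + lambda I) x = E s, with the forward
  # operator s = E^H x
  x <- complex(length(px))
  r <- E %*% ksamples
  p <- r
  rs <- Re(crossprod(Conj(r), r))
  for (it in seq_len(iters)) {
    Ap <- E %*% crossprod(Conj(E), p) + lambda * p
    alpha <- as.numeric(rs / Re(crossprod(Conj(p), Ap)))
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs2 <- Re(crossprod(Conj(r), r))
    if (rs2 < 1e-30) break
    p <- r + as.numeric(rs2 / rs) * p
    rs <- rs2
  }
  matrix(x, matrix, matrix)
}

#' Frequency-segmented off-resonance deblurring
#'
#' Conjugate-phase correction by multifrequency interpolation: the samples
#' are demodulated at `n_bins` frequencies spanning the B0 map range, each
#' demodulated set is gridded, and the final image interpolates per pixel
#' linearly between the two reconstructions whose bin frequencies bracket the
#' pixel's off-resonance. With a single bin and a zero map this is the plain
#' gridding path.
#'
#' @param ksamples Complex samples (concatenated arms).
#' @param traj A [make_spiral()] trajectory.
#' @param b0map Off-resonance map (Hz) on the output grid.
#' @param arm_indices 0-based arm index per arm.
#' @param n_bins Number of demodulation frequencies; defaults to the
#'   half-cycle rule `ceiling(range * readout / 500) + 1`, at least 5.
#' @param method Per-bin reconstruction method, see [grid_recon()].
#' @return Complex deblurred image.
#' @export
mfi_deblur <- function(ksamples, traj, b0map, arm_indices = 0, n_bins = NULL,
                       method = "adjoint") {
  stopifnot(all(is.finite(b0map)))
  fr <- range(b0map)
  if (is.null(n_bins)) {
    n_bins <- max(5, ceiling(diff(fr) * traj$readout_ms / 500) + 1)
  }
  if (n_bins < 1) stop("n_bins must be at least 1")
  if (diff(fr) == 0) n_bins <- 1L
  freqs <- if (n_bins == 1) mean(fr) else seq(fr[1], fr[2], length.out = n_bins)
  t_ms <- rep(traj$t_ms, times = length(arm_indices))
  recons <- lapply(freqs, function(f) {
    grid_recon(ksamples * exp(-2i * pi * f * t_ms / 1000), traj, arm_indices,
               method = method)
  })
  if (n_bins == 1) return(recons[[1]])
  stopifnot(all(dim(b0map) == dim(recons[[1]])))
  # per-pixel linear interpolation between bracketing bins
  step <- freqs[2] - freqs[1]
  pos <- (b0map - freqs[1]) / step
  lo <- pmin(pmax(floor(pos), 0), n_bins - 2)
  frac <- pos - lo
  out <- matrix(0 + 0i, nrow(b0map), ncol(b0map))
  for (b in seq_len(n_bins - 1)) {
    sel <- lo == (b - 1)
    if (any(sel)) {
      out[sel] <- recons[[b]][sel] * (1 - frac[sel]) +
        recons[[b + 1]][sel] * frac[sel]
    }
  }
  out
}

#' Write / read a trajectory as columnar text
#'
#' Four columns: kx, ky (cycles/mm), t (ms), dcf; header lines carry the
#' scalar fields.
#'
#' @param traj A [make_spiral()] trajectory.
#' @param path Output file.
#' @return `write_trajectory()` the path invisibly; `read_trajectory()` the
#'   restored trajectory.
#' @export
write_trajectory <- function(traj, path) {
  hdr <- sprintf("# fov_mm=%g matrix=%d readout_ms=%g n_arms_full=%d n_turns=%d te_ms=%g",
                 traj$fov_mm, traj$matrix, traj$readout_ms,
                 traj$n_arms_full, traj$n_turns, traj$te_ms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("kx ky t_ms dcf", con)
  utils::write.table(
    data.frame(kx = Re(traj$arm_k), ky = Im(traj$arm_k),
               t_ms = traj$t_ms, dcf = traj$dcf),
    con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- strsplit(sub("^#\\s*", "", hdr), "\\s+")[[1]]
  vals <- as.list(stats::setNames(
    as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv)))
  tab <- utils::read.table(path, skip = 2)
  out <- list(
    arm_k = complex(real = tab[[1]], imaginary = tab[[2]]),
    t_ms = tab[[3]], dcf = tab[[4]],
    n_arms_full = as.integer(vals$n_arms_full),
    rotation_deg_per_tr = 360 / vals$n_arms_full,
    fov_mm = vals$fov_mm, matrix = as.integer(vals$matrix),
    readout_ms = vals$readout_ms, n_turns = as.integer(vals$n_turns),
    te_ms = vals$te_ms
  )
  class(out) <- "spiral_trajectory"
  out
}
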