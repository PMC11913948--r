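#' Sequence configuration for the continuous inversion-recovery Look-Locker
#' acquisition
#'
#' Bundles every timing and geometry parameter of the single-shot spoiled
#' gradient-echo spiral sequence: one adiabatic inversion followed by an
#' uninterrupted train of small-flip excitations, one spiral arm per TR, with
#' two interleaved echo times.
#'
#' @param flip_deg Nominal excitation flip angle in degrees.
#' @param tr_ms Repetition time in ms.
#' @param n_excitations Number of RF excitations after the inversion. Must be
#'   even, because echo times alternate in TE1/TE2 pairs.
#' @param te1_ms,te2_ms Interleaved echo times in ms (`te1_ms < te2_ms < tr_ms`).
#' @param readout_ms Spiral readout duration in ms.
#' @param inv_efficiency Inversion factor in \[-1, 1\]; 1 corresponds to a
#'   perfect adiabatic inversion, 0 to no inversion.
#' @param ti_offset_ms Extra delay between the inversion and the first
#'   excitation, in ms.
#' @param slice_thickness_mm,slice_gap_mm Slice thickness and inter-slice gap
#'   in mm.
#' @param slices_per_stack Slices acquired in one breath-hold.
#' @param n_stacks Number of breath-hold stacks covering the organ.
#' @param overlap_slices Slices shared between consecutive stacks.
#' @param fov_mm In-plane field of view in mm.
#' @param matrix_size Reconstruction matrix size (square).
#'
#' @return An object of class `seq_config` (a validated list).
#' @examples
#' cfg <- seq_config()
#' sequence_timing(cfg)
#' @export
seq_config <- function(flip_deg = 5, tr_ms = 15, n_excitations = 100,
                       te1_ms = 2.3, te2_ms = 3.3, readout_ms = 9.2,
                       inv_efficiency = 1, ti_offset_ms = 0,
                       slice_thickness_mm = 5, slice_gap_mm = 1,
                       slices_per_stack = 8, n_stacks = 3, overlap_slices = 2,
                       fov_mm = 220, matrix_size = 110) {
  cfg <- list(
    flip_deg = flip_deg, tr_ms = tr_ms, n_excitations = as.integer(n_excitations),
    te1_ms = te1_ms, te2_ms = te2_ms, readout_ms = readout_ms,
    inv_efficiency = inv_efficiency, ti_offset_ms = ti_offset_ms,
    slice_thickness_mm = slice_thickness_mm, slice_gap_mm = slice_gap_mm,
    slices_per_stack = as.integer(slices_per_stack),
    n_stacks = as.integer(n_stacks),
    overlap_slices = as.integer(overlap_slices),
    fov_mm = fov_mm, matrix_size = as.integer(matrix_size)
  )
  class(cfg) <- "seq_config"
  validate_seq_config(cfg)
}

validate_seq_config <- function(cfg) {
  stopifnot(
    cfg$n_excitations >= 2,
    cfg$n_excitations %% 2L == 0L,
    cfg$te1_ms < cfg$te2_ms, cfg$te2_ms < cfg$tr_ms,
    cfg$readout_ms < cfg$tr_ms,
    cfg$inv_efficiency >= -1, cfg$inv_efficiency <= 1,
    cfg$ti_offset_ms >= 0,
    cfg$slice_thickness_mm > 0, cfg$slice_gap_mm >= 0,
    cfg$slices_per_stack >= 1, cfg$n_stacks >= 1,
    cfg$overlap_slices >= 0, cfg$overlap_slices < cfg$slices_per_stack,
    cfg$fov_mm > 0, cfg$matrix_size >= 2
  )
  cfg
}

#' @export
print.seq_config <- function(x, ...) {
  cat("<seq_config>\n")
  cat(sprintf("  flip %g deg, TR %g ms, %d excitations, TE %g/%g ms\n",
              x$flip_deg, x$tr_ms, x$n_excitations, x$te1_ms, x$te2_ms))
  cat(sprintf("  readout %g ms, inversion efficiency %g\n",
              x$readout_ms, x$inv_efficiency))
  cat(sprintf("  slices: %g mm + %g mm gap, %d per stack, %d stacks, overlap %d\n",
              x$slice_thickness_mm, x$slice_gap_mm, x$slices_per_stack,
              x$n_stacks, x$overlap_slices))
  cat(sprintf("  FOV %g mm, matrix %d\n", x$fov_mm, x$matrix_size))
  invisible(x)
}

#' Echo time of every excitation in acquisition order
#'
#' @param config A [seq_config()].
#' @return Numeric vector of length `n_excitations`, alternating TE1/TE2.
#' @export
te_schedule <- function(config) {
  rep(c(config$te1_ms, config$te2_ms), length.out = config$n_excitations)
}

#' Derived timing quantities of the multi-slice protocol
#'
#' Computes the per-slice train duration, whether one stack fits the stated
#' breath-hold, the acquired and unique slice counts across stacks, and the
#' inter-stack overlap thickness.
#'
#' @param config A [seq_config()].
#' @param breath_hold_s Available breath-hold duration in seconds.
#' @return A list with elements `train_ms`, `slice_s`, `stack_s`,
#'   `fits_breath_hold`, `slices_acquired`, `slices_unique`, `overlap_mm`.
#' @export
sequence_timing <- function(config, breath_hold_s = 12) {
  train_ms <- config$n_excitations * config$tr_ms
  slice_s <- train_ms / 1000
  stack_s <- slice_s * config$slices_per_stack
  acquired <- config$n_stacks * config$slices_per_stack
  unique_n <- acquired - (config$n_stacks - 1L) * config$overlap_slices
  overlap_mm <- if (config$overlap_slices > 0) {
    config$overlap_slices * config$slice_thickness_mm +
      (config$overlap_slices - 1L) * config$slice_gap_mm
  } else 0
  list(
    train_ms = train_ms,
    slice_s = slice_s,
    stack_s = stack_s,
    fits_breath_hold = stack_s <= breath_hold_s,
    slices_acquired = acquired,
    slices_unique = unique_n,
    overlap_mm = overlap_mm
  )
}

#' Excitation slice profile for dictionary simulation
#'
#' Discretizes the through-slice excitation profile into sub-slices, each with
#' a relative flip-angle scale (peak 1) and a relative inversion scale. The
#' default is the small-tip-angle profile of a Hamming-windowed sinc pulse
#' (time-bandwidth product `tbw`), evaluated over `extent` times the slice
#' thickness. The adiabatic inversion slab is assumed wider than the
#' excitation slice, so the inversion scale defaults to 1 everywhere.
#'
#' @param n_sub Number of sub-slices (odd values keep the slab center on a
#'   sample); at least 1.
#' @param tbw Time-bandwidth product of the excitation pulse.
#' @param extent Evaluated slab width as a multiple of the slice thickness.
#' @param rectangular If `TRUE`, return an ideal box profile (all scales 1),
#'   useful as an oracle.
#' @return An object of class `slice_profile`: list with `pos_rel` (sub-slice
#'   center positions, in units of slice thickness, symmetric about 0),
#'   `flip_scale` and `inv_scale`.
#' @export
slice_profile <- function(n_sub = 21, tbw = 4, extent = 2, rectangular = FALSE) {
  stopifnot(n_sub >= 1, tbw > 0, extent > 0)
  pos <- if (n_sub == 1) 0 else seq(-extent / 2, extent / 2, length.out = n_sub)
  if (rectangular) {
    fs <- rep(1, n_sub)
  } else {
    # small-tip profile: Fourier transform of the windowed RF envelope.
    nt <- 513
    t <- seq(-0.5, 0.5, length.out = nt)
    env <- sinc(tbw * t) * (0.54 + 0.46 * cos(2 * pi * t))
    # position u (slice-thickness units) maps to frequency u * tbw
    fs <- vapply(pos, function(u) {
      sum(env * cos(2 * pi * (u * tbw) * t))
    }, numeric(1))
    fs <- fs / max(fs)
    fs <- pmin(pmax(fs, 0), 1)
  }
  out <- list(pos_rel = pos, flip_scale = fs, inv_scale = rep(1, n_sub))
  class(out) <- "slice_profile"
  out
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

validate_slice_profile <- function(profile) {
  stopifnot(
    length(profile$flip_scale) >= 1,
    length(profile$flip_scale) == length(profile$inv_scale),
    all(profile$flip_scale >= 0), all(profile$flip_scale <= 1)
  )
  invisible(profile)
}

#' Interleaved slice acquisition order within a stack
#'
#' Slices are acquired with a stride of 3 to keep neighbouring slices apart
#' in time (for 8 slices: 1, 4, 7, 2, 5, 8, 3, 6).
#'
#' @param slices_per_stack Number of slices in the stack.
#' @return Integer vector: acquisition order (1-based slice indices).
#' @export
interleave_order <- function(slices_per_stack) {
  stopifnot(slices_per_stack >= 1)
  n <- as.integer(slices_per_stack)
  unlist(lapply(1:3, function(s) if (s <= n) seq.int(s, n, by = 3L) else integer(0)))
}

# Deterministic hash of an R object (used for config/profile provenance).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  # version = 2 keeps the serialization stable across R sessions
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
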