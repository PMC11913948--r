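# Core EPG engine, vectorized over columns so that a whole T1 grid (and all
# sub-slices of a profile) evolve in one pass. Each column is one isochromat
# population with its own T1, flip angle and inversion factor; T2 is shared.
#
# States follow the usual (F+, F-, Z) configuration bookkeeping: per TR the
# RF mixing matrix is applied, the freshly formed F+(0) is recorded at the
# echo time (scaled by exp(-TE/T2)), then relaxation over the full TR and one
# unit gradient-dephasing shift. `ideal` spoiling crushes all transverse
# states after sampling, which reduces exactly to the longitudinal
# Look-Locker recursion.
epg_train_cols <- function(t1_ms, t2_ms, flip_deg, inv_factor, config,
                           spoiling_mode = "gradient_spoiled") {
  n <- config$n_excitations
  nc <- length(t1_ms)
  stopifnot(length(flip_deg) == nc, length(inv_factor) == nc,
            all(t1_ms > 0), t2_ms > 0, n >= 2)
  spoiling_mode <- match.arg(spoiling_mode, c("gradient_spoiled", "ideal"))

  a <- flip_deg * pi / 180
  te <- te_schedule(config)
  E2te <- exp(-te / t2_ms)

  if (spoiling_mode == "ideal") {
    # crushing all transverse magnetization after each echo reduces the EPG
    # to the longitudinal Look-Locker recursion; run it directly
    E1 <- exp(-config$tr_ms / t1_ms)
    rec <- 1 - E1
    sa <- sin(a)
    ca <- cos(a)
    mz <- -config$inv_efficiency * inv_factor
    if (config$ti_offset_ms > 0) {
      e1i <- exp(-config$ti_offset_ms / t1_ms)
      mz <- 1 + (mz - 1) * e1i
    }
    sig <- matrix(0 + 0i, n, nc)
    for (j in seq_len(n)) {
      sig[j, ] <- -1i * sa * mz * E2te[j]
      mz <- (mz * ca) * E1 + rec
    }
    return(sig)
  }

  # truncating the dephasing order costs at most E2^max_order in relative
  # amplitude, far below solver precision for the trains simulated here
  K <- min(n, max_epg_order(config$tr_ms, t2_ms)) + 1L
  rowmat <- function(v) matrix(v, nrow = K, ncol = nc, byrow = TRUE)
  c2 <- rowmat(cos(a / 2)^2)
  s2 <- rowmat(sin(a / 2)^2)
  sa <- rowmat(sin(a))
  ca <- rowmat(cos(a))

  E1 <- exp(-config$tr_ms / t1_ms)      # per column
  E2 <- exp(-config$tr_ms / t2_ms)      # scalar
  rec <- 1 - E1

  Fp <- matrix(0 + 0i, K, nc)
  Fm <- matrix(0 + 0i, K, nc)
  Z <- matrix(0 + 0i, K, nc)
  Z[1, ] <- -config$inv_efficiency * inv_factor
  if (config$ti_offset_ms > 0) {
    e1i <- exp(-config$ti_offset_ms / t1_ms)
    Z[1, ] <- 1 + (Z[1, ] - 1) * e1i
  }

  sig <- matrix(0 + 0i, n, nc)
  for (j in seq_len(n)) {
    Fp2 <- c2 * Fp + s2 * Fm - 1i * sa * Z
    Fm2 <- s2 * Fp + c2 * Fm + 1i * sa * Z
    Z2 <- -0.5i * sa * Fp + 0.5i * sa * Fm + ca * Z
    Fp <- Fp2; Fm <- Fm2; Z <- Z2

    sig[j, ] <- Fp[1, ] * E2te[j]

    Fp <- Fp * E2
    Fm <- Fm * E2
    Z <- Z * rep(E1, each = K)
    Z[1, ] <- Z[1, ] + rec
    # one unit dephasing: F+ orders move up, F- orders move down
    Fp[2:K, ] <- Fp[1:(K - 1), ]
    Fm[1:(K - 1), ] <- Fm[2:K, ]
    Fm[K, ] <- 0 + 0i
    Fp[1, ] <- Conj(Fm[1, ])
  }
  sig
}

# Dephasing orders worth tracking: a state of order k must survive 2k TRs of
# T2 decay to return to the echo line, so orders with E2^(2k) below `tol`
# cannot contribute at numerical precision.
max_epg_order <- function(tr_ms, t2_ms, tol = 1e-11) {
  max(2L, as.integer(ceiling(-log(tol) * t2_ms / (2 * tr_ms))))
}

#' Simulate one inversion-prepared Look-Locker excitation train
#'
#' Runs the Extended Phase Graph (EPG) simulation of the continuous
#' inversion-recovery sequence: an inversion (scaled by
#' `config$inv_efficiency`), then `config$n_excitations` excitations of
#' `flip_deg` every `tr_ms`, sampling the transverse signal at the alternating
#' echo times. With `spoiling_mode = "ideal"` all transverse magnetization is
#' crushed after each echo, which is exactly the closed-form Look-Locker
#' recursion on the longitudinal component; `"gradient_spoiled"` keeps the
#' full configuration-state evolution with one dephasing increment per TR.
#'
#' @param t1_ms,t2_ms Relaxation times in ms (both > 0). `t1_ms` may be a
#'   vector, in which case a matrix with one column per T1 is returned.
#' @param flip_deg Excitation flip angle in degrees.
#' @param config A [seq_config()].
#' @param spoiling_mode `"gradient_spoiled"` (default) or `"ideal"`.
#' @return Complex vector of length `n_excitations` (or a matrix
#'   `n_excitations x length(t1_ms)`).
#' @examples
#' cfg <- seq_config()
#' s <- epg_simulate_train(1000, 50, 5, cfg)
#' @export
epg_simulate_train <- function(t1_ms, t2_ms, flip_deg, config,
                               spoiling_mode = "gradient_spoiled") {
  if (any(t1_ms <= 0) || t2_ms <= 0) stop("relaxation times must be positive")
  nc <- length(t1_ms)
  sig <- epg_train_cols(t1_ms, t2_ms, rep(flip_deg, nc), rep(1, nc),
                        config, spoiling_mode)
  if (nc == 1) drop(sig) else sig
}

#' Simulate the train including slice-profile effects
#'
#' Runs [epg_simulate_train()] for every sub-slice of the excitation profile,
#' with the flip angle scaled by the sub-slice flip factor and the inversion
#' by the sub-slice inversion factor, and returns the unweighted complex sum
#' over sub-slices (the integrated slab signal).
#'
#' @inheritParams epg_simulate_train
#' @param profile A [slice_profile()].
#' @param b1_fraction Global transmit-field scale applied to the flip angle.
#' @return Complex vector of length `n_excitations` (or matrix, one column
#'   per T1).
#' @export
simulate_with_profile <- function(t1_ms, t2_ms, config, profile,
                                  b1_fraction = 1,
                                  spoiling_mode = "gradient_spoiled") {
  validate_slice_profile(profile)
  if (any(t1_ms <= 0) || t2_ms <= 0) stop("relaxation times must be positive")
  ns <- length(profile$flip_scale)
  nt <- length(t1_ms)
  # one column per (T1, sub-slice) pair, simulated in a single EPG pass
  t1_cols <- rep(t1_ms, times = ns)
  flip_cols <- config$flip_deg * b1_fraction * rep(profile$flip_scale, each = nt)
  inv_cols <- rep(profile$inv_scale, each = nt)
  sig <- epg_train_cols(t1_cols, t2_ms, flip_cols, inv_cols, config,
                        spoiling_mode)
  dim(sig) <- c(config$n_excitations, nt, ns)
  out <- sig[, , 1]
  if (ns > 1) for (k in 2:ns) out <- out + sig[, , k]
  if (nt == 1) drop(out) else out
}

#' Collapse interleaved TE pairs to one sample per TR pair
#'
#' The acquisition interleaves two echo times, so the raw dictionary vectors
#' have `n_excitations` points. After water-fat separation only one effective
#' sample per TE pair is needed; this keeps the first (TE1-indexed) sample of
#' each consecutive pair, halving the length.
#'
#' Alternatively, `weights = c(w1, w2)` collapses each pair to the affine
#' combination `w1 s1 + w2 s2`; with the separation weights
#' `(1 + lambda, -lambda)`, `lambda = c_F(TE1) / (c_F(TE2) - c_F(TE1))`, the
#' collapsed vector equals what the two-point water-fat separation returns
#' for a pure-water train (see [build_dictionary()]'s `collapse = "matched"`).
#'
#' @param signal Complex (or numeric) vector or matrix (signals in columns)
#'   of even length.
#' @param weights Optional complex pair weights; `NULL` keeps the first
#'   sample of each pair.
#' @return The input with every pair collapsed to one sample.
#' @export
collapse_te_pairs <- function(signal, weights = NULL) {
  vec <- !is.matrix(signal)
  if (vec) signal <- matrix(signal, ncol = 1)
  n <- nrow(signal)
  if (n %% 2L != 0L) stop("signal length must be even")
  i1 <- seq.int(1L, n, by = 2L)
  out <- if (is.null(weights)) {
    signal[i1, , drop = FALSE]
  } else {
    stopifnot(length(weights) == 2)
    weights[1] * signal[i1, , drop = FALSE] +
      weights[2] * signal[i1 + 1L, , drop = FALSE]
  }
  if (vec) drop(out) else out
}

#' Build the T1 matching dictionary
#'
#' Simulates the slab-integrated signal train for every T1 on a regular grid,
#' collapses the interleaved TE pairs and normalizes each vector to unit
#' Euclidean norm. With the default sequence this yields 581 complex atoms of
#' length 50 for T1 from 100 to 3000 ms in steps of 5 ms, simulated at a
#' fixed T2 of 50 ms and nominal transmit field (the small-flip train encodes
#' neither T2 nor B1 to first order).
#'
#' The default TE-pair collapse keeps the TE1-indexed samples. Because the
#' two echoes of a pair come from consecutive excitations, the separated
#' water signal is actually a complex affine combination of the pair;
#' `collapse = "matched"` builds the dictionary with exactly those
#' separation weights (derived from `fat_model` and the configured echo
#' times), which removes the small systematic wT1 underestimate of the
#' TE1-only collapse for fat-free tissue.
#'
#' @param config A [seq_config()].
#' @param profile A [slice_profile()]; defaults to the windowed-sinc profile.
#' @param t1_min,t1_max,t1_step T1 grid in ms.
#' @param t2_ms Simulation T2 in ms.
#' @param b1_fraction Transmit-field scale.
#' @param spoiling_mode Passed to the EPG simulation.
#' @param collapse `"te1"` (keep TE1 samples, default) or `"matched"`
#'   (separation-consistent pair weights).
#' @param fat_model Fat model used to derive the `"matched"` weights.
#' @return An object of class `wt1_dictionary`: list with `t1_grid_ms`,
#'   `atoms` (complex matrix, one unit-norm column per T1) and `meta`.
#' @examples
#' \donttest{
#' d <- build_dictionary(seq_config())
#' dim(d$atoms)  # 50 x 581
#' }
#' @export
build_dictionary <- function(config, profile = slice_profile(),
                             t1_min = 100, t1_max = 3000, t1_step = 5,
                             t2_ms = 50, b1_fraction = 1,
                             spoiling_mode = "gradient_spoiled",
                             collapse = c("te1", "matched"),
                             fat_model = fat_model_7peak()) {
  stopifnot(t1_min < t1_max, t1_step > 0)
  collapse <- match.arg(collapse)
  grid <- seq(t1_min, t1_max, by = t1_step)
  sig <- simulate_with_profile(grid, t2_ms, config, profile, b1_fraction,
                               spoiling_mode)
  weights <- NULL
  if (collapse == "matched") {
    c1 <- fat_phasor(fat_model, config$te1_ms)
    c2 <- fat_phasor(fat_model, config$te2_ms)
    lambda <- c1 / (c2 - c1)
    weights <- c(1 + lambda, -lambda)
  }
  atoms <- collapse_te_pairs(sig, weights)
  nrm <- sqrt(colSums(Mod(atoms)^2))
  if (any(nrm == 0)) stop("degenerate dictionary atom (zero norm)")
  atoms <- sweep(atoms, 2, nrm, "/")
  out <- list(
    t1_grid_ms = grid,
    atoms = atoms,
    meta = list(
      t2_ms = t2_ms, b1_fraction = b1_fraction,
      spoiling_mode = spoiling_mode, collapse = collapse,
      config_hash = object_hash(config),
      profile_hash = object_hash(profile)
    )
  )
  class(out) <- "wt1_dictionary"
  out
}

#' @export
print.wt1_dictionary <- function(x, ...) {
  cat(sprintf(
    "<wt1_dictionary> %d atoms of length %d, T1 %g..%g ms (T2 %g ms)\n",
    length(x$t1_grid_ms), nrow(x$atoms),
    min(x$t1_grid_ms), max(x$t1_grid_ms), x$meta$t2_ms))
  invisible(x)
}

#' Persist / load a dictionary as portable text
#'
#' The atom matrix is written as real/imaginary CSV columns next to a JSON
#' sidecar holding the T1 grid and simulation metadata, so the container is
#' plain text and platform independent.
#'
#' @param dict A `wt1_dictionary`.
#' @param path Base path; `<path>.csv` and `<path>.json` are written.
#' @return `write_dictionary()` the base path, invisibly;
#'   `read_dictionary()` the restored `wt1_dictionary`.
#' @export
write_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "wt1_dictionary"))
  tab <- data.frame(Re(dict$atoms), Im(dict$atoms))
  names(tab) <- c(paste0("re_", seq_along(dict$t1_grid_ms)),
                  paste0("im_", seq_along(dict$t1_grid_ms)))
  utils::write.csv(tab, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(t1_grid_ms = dict$t1_grid_ms, meta = dict$meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- utils::read.csv(paste0(path, ".csv"))
  k <- length(side$t1_grid_ms)
  atoms <- as.matrix(tab[, 1:k]) + 1i * as.matrix(tab[, (k + 1):(2 * k)])
  dimnames(atoms) <- NULL
  out <- list(t1_grid_ms = side$t1_grid_ms, atoms = atoms, meta = side$meta)
  class(out) <- "wt1_dictionary"
  out
}
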