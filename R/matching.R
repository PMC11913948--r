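#' Match one signal to the dictionary
#'
#' Computes the magnitude of the normalized complex inner product between the
#' signal and every dictionary atom and returns the T1 of the best-matching
#' atom together with the match quality (the maximum, in \[0, 1\]). The
#' magnitude (not the real part) is maximized, so a global complex scaling of
#' the signal — arbitrary coil phase and amplitude — does not change the
#' match. Ties resolve to the lower T1.
#'
#' @param signal Complex vector, same length as the dictionary atoms.
#' @param dictionary A [build_dictionary()] result.
#' @return List with `t1_ms` and `quality`; a zero-norm signal returns
#'   `t1_ms = NA` and `quality = 0`.
#' @export
match_signal <- function(signal, dictionary) {
  stopifnot(inherits(dictionary, "wt1_dictionary"),
            length(signal) == nrow(dictionary$atoms))
  nrm <- sqrt(sum(Mod(signal)^2))
  if (nrm == 0) return(list(t1_ms = NA_real_, quality = 0))
  ip <- Mod(crossprod(Conj(dictionary$atoms), signal / nrm))
  best <- which.max(ip)  # first maximum = lowest T1 on the ascending grid
  list(t1_ms = dictionary$t1_grid_ms[best], quality = as.numeric(ip[best]))
}

#' Match every pixel of a water image series
#'
#' Per-pixel dictionary matching of a separated water series. Background
#' pixels — mean signal magnitude below `mask_threshold` times the 95th
#' percentile of the mean magnitude — are masked out, as are zero-norm
#' pixels.
#'
#' @param water Complex array `(x, y, n)` (e.g. `$water` of
#'   [separate_series()]), or a `water_fat_result`.
#' @param dictionary A [build_dictionary()] result.
#' @param mask Optional logical matrix restricting the matched pixels.
#' @param mask_threshold Background threshold as a fraction of the
#'   95th-percentile mean signal magnitude; set to 0 to disable.
#' @return An object of class `wt1_map`: list with numeric matrices `wt1_ms`
#'   (NA where masked), `quality` and logical `mask`.
#' @export
match_image <- function(water, dictionary, mask = NULL, mask_threshold = 0.05) {
  if (inherits(water, "water_fat_result")) water <- water$water
  stopifnot(length(dim(water)) == 3,
            dim(water)[3] == nrow(dictionary$atoms))
  d <- dim(water)
  np <- d[1] * d[2]
  X <- matrix(water, np, d[3])
  mag <- rowMeans(Mod(X))
  keep <- mag > 0
  if (mask_threshold > 0 && any(keep)) {
    thr <- mask_threshold * stats::quantile(mag, 0.95, names = FALSE)
    keep <- keep & mag >= thr
  }
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == d[1:2]))
    keep <- keep & as.vector(mask)
  }
  wt1 <- matrix(NA_real_, d[1], d[2])
  quality <- matrix(0, d[1], d[2])
  if (any(keep)) {
    Xk <- X[keep, , drop = FALSE]
    Xk <- Xk / sqrt(rowSums(Mod(Xk)^2))
    ip <- Mod(Xk %*% Conj(dictionary$atoms))
    best <- max.col(ip, ties.method = "first")
    wt1[keep] <- dictionary$t1_grid_ms[best]
    quality[keep] <- ip[cbind(seq_len(nrow(ip)), best)]
  }
  out <- list(wt1_ms = wt1, quality = quality,
              mask = matrix(keep, d[1], d[2]))
  class(out) <- "wt1_map"
  out
}

#' @export
print.wt1_map <- function(x, ...) {
  v <- x$wt1_ms[x$mask]
  cat(sprintf("<wt1_map> %d x %d, %d matched pixels, wT1 %s ms\n",
              nrow(x$wt1_ms), ncol(x$wt1_ms), sum(x$mask),
              if (length(v)) sprintf("%.0f-%.0f", min(v), max(v)) else "-"))
  invisible(x)
}

#' Assemble per-stack slice maps into a whole-organ volume
#'
#' Concatenates the stacks in order, resolving the deliberate inter-stack
#' slice overlap. `keep_first` (default) drops the duplicated leading slices
#' of each later stack, `keep_second` drops the trailing slices of the
#' earlier stack, `average` averages the overlapping pairs.
#'
#' @param stacks List of numeric 3D arrays `(x, y, slices_per_stack)`, in
#'   stack order.
#' @param overlap_slices Slices shared between consecutive stacks.
#' @param strategy One of `"keep_first"`, `"keep_second"`, `"average"`.
#' @return List with `volume` (numeric 3D array of unique slices) and
#'   `provenance` (data frame: output slice, contributing stack(s) and
#'   within-stack indices).
#' @export
assemble_stacks <- function(stacks, overlap_slices,
                            strategy = c("keep_first", "keep_second", "average")) {
  strategy <- match.arg(strategy)
  stopifnot(length(stacks) >= 1)
  dims <- lapply(stacks, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop("inconsistent stack geometry")
  }
  sps <- dims[[1]][3]
  stopifnot(overlap_slices >= 0, overlap_slices < sps)
  ns <- length(stacks)
  n_out <- ns * sps - (ns - 1) * overlap_slices

  vol <- array(NA_real_, c(dims[[1]][1], dims[[1]][2], n_out))
  prov <- data.frame(slice = seq_len(n_out), stack = NA_integer_,
                     stack_slice = NA_integer_, averaged = FALSE)
  for (s in seq_len(ns)) {
    start <- (s - 1) * (sps - overlap_slices)  # 0-based position of slice 1
    for (j in seq_len(sps)) {
      pos <- start + j
      fresh <- is.na(prov$stack[pos])
      if (fresh) {
        vol[, , pos] <- stacks[[s]][, , j]
        prov$stack[pos] <- s
        prov$stack_slice[pos] <- j
      } else if (strategy == "keep_second") {
        vol[, , pos] <- stacks[[s]][, , j]
        prov$stack[pos] <- s
        prov$stack_slice[pos] <- j
      } else if (strategy == "average") {
        vol[, , pos] <- (vol[, , pos] + stacks[[s]][, , j]) / 2
        prov$averaged[pos] <- TRUE
      } # keep_first: leave the earlier stack's slice
    }
  }
  list(volume = vol, provenance = prov)
}
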