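GAMMA_MHZ_PER_T <- 42.577  # 1H gyromagnetic ratio / 2pi

#' Multi-peak fat spectral model
#'
#' A fat model is a set of resonances at fixed chemical shifts relative to
#' water with fixed relative amplitudes (normalized to sum 1) at a given
#' field strength. It determines the complex fat phasor used by the two-echo
#' water-fat separation and by the composite-signal forward model.
#'
#' `fat_model_7peak()` is a liver-type in vivo triglyceride model and
#' `fat_model_peanut10()` a 10-peak model for peanut-oil emulsion phantoms;
#' both are nominal spectra derived from standard triglyceride proton
#' bookkeeping (chain length / double-bond counts typical of the tissue or
#' oil) and can be overridden with measured tables via `fat_model()`.
#'
#' @param peak_shift_ppm Chemical shifts relative to water (ppm, negative
#'   upfield of water).
#' @param rel_amplitudes Relative amplitudes; normalized internally to sum 1.
#' @param field_T Main field strength in Tesla.
#' @param name Model label.
#' @return An object of class `fat_model`.
#' @examples
#' fm <- fat_model_7peak()
#' fat_phasor(fm, c(2.3, 3.3))
#' @export
fat_model <- function(peak_shift_ppm, rel_amplitudes, field_T = 3,
                      name = "custom") {
  stopifnot(length(peak_shift_ppm) == length(rel_amplitudes),
            length(peak_shift_ppm) >= 1,
            all(rel_amplitudes >= 0), sum(rel_amplitudes) > 0,
            field_T > 0)
  out <- list(
    name = name,
    peak_shift_ppm = peak_shift_ppm,
    rel_amplitudes = rel_amplitudes / sum(rel_amplitudes),
    field_T = field_T
  )
  class(out) <- "fat_model"
  out
}

# Triglyceride proton counts for chain length cl, double bonds ndb and
# methylene-interrupted double bonds nmidb (per molecule, 9 resonances;
# glycerol CH2 split into two peaks for the 10-peak variant).
triglyceride_protons <- function(cl, ndb, nmidb, split_glycerol = FALSE) {
  peaks <- c(
    olefinic   = 2 * ndb,                         # 5.29 ppm
    glycerolCH = 1,                               # 5.19 ppm
    diallylic  = 2 * nmidb,                       # 2.75 ppm
    alpha      = 6,                               # 2.24 ppm
    allylic    = 4 * (ndb - nmidb),               # 2.02 ppm
    beta       = 6,                               # 1.60 ppm
    methylene  = 6 * (cl - 4) - 8 * ndb + 2 * nmidb,  # 1.30 ppm
    methyl     = 9                                # 0.90 ppm
  )
  ppm <- c(5.29, 5.19, 2.75, 2.24, 2.02, 1.60, 1.30, 0.90)
  if (split_glycerol) {
    peaks <- c(peaks[1:2], glycerolA = 2, glycerolB = 2, peaks[3:8])
    ppm <- c(ppm[1:2], 4.30, 4.12, ppm[3:8])
  } else {
    peaks <- c(peaks[1:2], glycerol = 4, peaks[3:8])
    ppm <- c(ppm[1:2], 4.20, ppm[3:8])
  }
  list(shift_ppm = ppm - 4.70, amp = unname(peaks))
}

#' @rdname fat_model
#' @export
fat_model_7peak <- function(field_T = 3) {
  # liver-type composition; beta-carboxyl merged into the methylene peak
  tg <- triglyceride_protons(cl = 17.4, ndb = 2.7, nmidb = 0.8)
  amp <- tg$amp
  shift <- tg$shift_ppm
  amp[1] <- amp[1] + amp[2]  # glycerol CH folded into the olefinic peak
  amp[8] <- amp[8] + amp[7]  # beta-carboxyl folded into the methylene peak
  keep <- c(1, 3, 4, 5, 6, 8, 9)
  fat_model(shift[keep], amp[keep], field_T, name = "7peak_invivo")
}

#' @rdname fat_model
#' @export
fat_model_peanut10 <- function(field_T = 3) {
  # peanut oil: ~ 50% oleic / 30% linoleic acids
  tg <- triglyceride_protons(cl = 17.8, ndb = 3.5, nmidb = 1.1,
                             split_glycerol = TRUE)
  fat_model(tg$shift_ppm, tg$amp, field_T, name = "10peak_peanut_oil")
}

#' @export
print.fat_model <- function(x, ...) {
  cat(sprintf("<fat_model> %s at %g T, %d peaks\n", x$name, x$field_T,
              length(x$peak_shift_ppm)))
  print(data.frame(shift_ppm = x$peak_shift_ppm,
                   rel_amplitude = round(x$rel_amplitudes, 4)))
  invisible(x)
}

#' Complex fat phasor at one or more echo times
#'
#' Evaluates `c_F(TE) = sum_p a_p exp(i 2 pi f_p TE)` with
#' `f_p = shift_ppm_p * 42.577 MHz/T * field_T`. Its magnitude is bounded by
#' 1 and equals 1 exactly at TE = 0.
#'
#' @param model A [fat_model()].
#' @param te_ms Echo time(s) in ms.
#' @return Complex vector of the same length as `te_ms`.
#' @export
fat_phasor <- function(model, te_ms) {
  stopifnot(inherits(model, "fat_model"))
  f_hz <- model$peak_shift_ppm * GAMMA_MHZ_PER_T * model$field_T  # ppm*MHz = Hz
  vapply(te_ms, function(te) {
    sum(model$rel_amplitudes * exp(2i * pi * f_hz * te / 1000))
  }, complex(1))
}
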