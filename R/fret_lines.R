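# Static and dynamic FRET lines in the (mean lifetime, efficiency) plane.
# Conformationally static molecules fall on the static line; molecules
# exchanging between two limiting states faster than the burst duration fall
# on the dynamic line connecting those states.

#' Static FRET line
#'
#' For ideal dyes, `E = 1 - tau/tau0`. A linker-correction polynomial can be
#' supplied (coefficients of increasing power, applied to the observed mean
#' lifetime before the ideal relation) as a calibration hook for empirically
#' determined line parameters; the default zero coefficients give the ideal
#' line.
#'
#' @param pair A [dye_pair()] providing `tau0`.
#' @param linker_coeffs Polynomial coefficients `c0, c1, ...`; the corrected
#'   lifetime is `tau + c0 + c1*tau + c2*tau^2 + ...` (all zero by default).
#' @return An object of class `fret_line` with an `$evaluate(tau)` function.
#' @export
static_fret_line <- function(pair, linker_coeffs = 0) {
  tau0 <- pair$tau0
  ev <- function(tau) {
    corr <- tau
    for (k in seq_along(linker_coeffs))
      corr <- corr + linker_coeffs[k] * tau^(k - 1)
    1 - corr / tau0
  }
  structure(list(kind = "static", tau0 = tau0, linker_coeffs = linker_coeffs,
                 evaluate = ev),
            class = "fret_line")
}

#' Dynamic FRET line between two limiting species
#'
#' Moment identity for a two-component lifetime mixture: a molecule
#' exchanging rapidly between species 1 and 2 has
#' \deqn{E(\langle\tau\rangle_F) = 1 - \frac{\tau_1 \tau_2}
#'   {\tau_0 (\tau_1 + \tau_2 - \langle\tau\rangle_F)}}
#' for fluorescence-weighted mean lifetimes between \eqn{\tau_1} and
#' \eqn{\tau_2}. The endpoints reproduce each species' static
#' \eqn{(\tau_i, E_i)}, so the dynamic line meets the static line there.
#'
#' @param s1,s2 Two [fret_species()] with distinct lifetimes.
#' @param pair The common [dye_pair()].
#' @return A `fret_line` whose `$evaluate(tau_f)` errors outside
#'   `[min(tau1, tau2), max(tau1, tau2)]`.
#' @export
dynamic_fret_line <- function(s1, s2, pair) {
  t1 <- s1$tau_DA; t2 <- s2$tau_DA
  if (abs(t1 - t2) < 1e-12) stop("species lifetimes must differ")
  tau0 <- pair$tau0
  lo <- min(t1, t2); hi <- max(t1, t2)
  ev <- function(tau_f) {
    if (any(tau_f < lo - 1e-9 | tau_f > hi + 1e-9))
      stop("mean lifetime outside the two-species range")
    1 - (t1 * t2) / (tau0 * (t1 + t2 - tau_f))
  }
  structure(list(kind = "dynamic", tau0 = tau0,
                 endpoints = list(s1 = s1, s2 = s2), evaluate = ev),
            class = "fret_line")
}

#' @export
print.fret_line <- function(x, ...) {
  cat(sprintf("<fret_line> %s (tau0 = %g ns)\n", x$kind, x$tau0))
  invisible(x)
}
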