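#' Monoisotopic atomic masses
#'
#' Standard monoisotopic masses (Da) of the elements supported by the
#' building-block registry. All peptide mass arithmetic in the package is
#' monoisotopic; there is no average-mass mode.
#'
#' @format Named numeric vector over C, H, N, O, S.
#' @export
ATOMIC_MASS <- c(
  C = 12.0000000,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

#' Mass constants used throughout the pipeline
#'
#' Returns the fixed constants that charge-state arithmetic, isotopic-envelope
#' summation and retro-Diels-Alder (RDA) companion prediction rely on:
#'
#' * `proton` (1.00728 Da): mass added per charge for protonated species.
#' * `isotope_spacing` (1.00335 Da): spacing of successive isotopologues of a
#'   singly-charged ion.
#' * `rda_loss` (default 303.13 Da): neutral loss of the in-source
#'   retro-Diels-Alder rearrangement of the pyoverdine chromophore, which
#'   produces a fixed-offset companion ion below every singly-charged
#'   precursor. The default is the difference of the native precursor/companion
#'   pair (m/z 1334.79 / 1031.66); it is configurable because the
#'   rearrangement's elemental composition is not modeled.
#' * `water` (18.01056 Da): restored at a free C-terminus of linear scaffolds.
#'
#' @param rda_loss Neutral RDA loss in Da.
#' @return A named list of positive numerics.
#' @examples
#' mass_constants()$proton
#' @export
mass_constants <- function(rda_loss = 303.13) {
  stopifnot(is.numeric(rda_loss), length(rda_loss) == 1, rda_loss >= 0)
  list(
    proton = 1.00728,
    isotope_spacing = 1.00335,
    rda_loss = rda_loss,
    water = 18.01056
  )
}

# default matching tolerances (Da) by instrument mode; MALDI reflectron
# cross-spectrum calibration offsets reach ~0.3 Da, ESI agrees to ~5 mDa
default_tolerance <- function(mode = c("MALDI", "ESI")) {
  mode <- match.arg(mode)
  c(MALDI = 0.3, ESI = 0.02)[[mode]]
}
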