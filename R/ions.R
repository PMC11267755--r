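#' Protonated m/z from a neutral mass
#'
#' `mz = (M + z * 1.00728) / z`. Only proton adducts are modeled; the study's
#' spectra use z = 1 (MALDI) and z = 2 (ESI precursors).
#'
#' @param m Neutral monoisotopic mass (Da); vectorized.
#' @param z Positive integer charge.
#' @return m/z in Da per charge.
#' @examples
#' ion_mz(1333.59, 2)  # the ESI doubly-charged native PVD precursor, ~667.8
#' @export
ion_mz <- function(m, z = 1L) {
  if (!is.numeric(z) || length(z) != 1 || z < 1 || z != round(z)) {
    stop("charge z must be a positive integer", call. = FALSE)
  }
  (m + z * mass_constants()$proton) / z
}

#' Retro-Diels-Alder companion m/z
#'
#' The pyoverdine chromophore undergoes an in-source retro-Diels-Alder
#' rearrangement producing a companion ion at a fixed neutral-loss offset
#' below each singly-charged precursor (native pair m/z 1334.79 -> 1031.66).
#'
#' @param mz Singly-charged precursor m/z; vectorized.
#' @param z Charge; must be 1 (the companion is defined on singly-charged
#'   species).
#' @param rda_loss Neutral loss in Da (default 303.13, the difference of the
#'   printed native pair).
#' @return Companion m/z.
#' @examples
#' rda_companion(1334.79)  # 1031.66
#' @export
rda_companion <- function(mz, z = 1L, rda_loss = 303.13) {
  if (z != 1L) stop("RDA companion is defined on singly-charged species (z = 1)",
                    call. = FALSE)
  out <- mz - rda_loss
  if (any(out <= 0)) stop("RDA companion m/z must be positive", call. = FALSE)
  out
}

#' Precursor-ion table for a set of variants
#'
#' For each variant: `[M+zH]z+` at the requested charges, plus (optionally)
#' the retro-Diels-Alder companion of the singly-charged species.
#'
#' @param variants A tibble from [enumerate_variants()], a list of
#'   `pvd_variant`, or a single `pvd_variant`.
#' @param charges Integer charges (default `c(1, 2)`).
#' @param rda Include RDA companions of the z = 1 ions.
#' @param rda_loss Neutral RDA loss in Da.
#' @param registry Registry tibble.
#' @return A tibble `label`, `z`, `mz`, `is_rda_companion`, `neutral_mass`,
#'   sorted by `mz`.
#' @export
precursor_table <- function(variants, charges = c(1L, 2L), rda = TRUE,
                            rda_loss = 303.13, registry = default_registry()) {
  if (inherits(variants, "pvd_variant")) variants <- list(variants)
  if (is.data.frame(variants)) {
    labels <- variants$label
    vlist <- variants$variant
    mass <- variants$neutral_mass %||%
      vapply(vlist, neutral_mass, numeric(1), registry = registry)
  } else {
    vlist <- variants
    labels <- vapply(vlist, `[[`, character(1), "label")
    mass <- vapply(vlist, neutral_mass, numeric(1), registry = registry)
  }
  charges <- sort(unique(as.integer(charges)))
  stopifnot(all(charges >= 1))
  rows <- purrr::map_dfr(seq_along(labels), function(i) {
    main <- tibble::tibble(
      label = labels[i], z = charges,
      mz = vapply(charges, function(z) ion_mz(mass[i], z), numeric(1)),
      is_rda_companion = FALSE, neutral_mass = mass[i]
    )
    if (rda && 1L %in% charges) {
      main <- dplyr::bind_rows(main, tibble::tibble(
        label = labels[i], z = 1L,
        mz = rda_companion(ion_mz(mass[i], 1L), rda_loss = rda_loss),
        is_rda_companion = TRUE, neutral_mass = mass[i]
      ))
    }
    main
  })
  dplyr::arrange(rows, .data$mz)
}
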