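#' Generate a labeled specificity-code sequence set
#'
#' Seeded generator emulating the structure of a categorized A-domain code
#' alignment: `n_t` threonine-specific and `n_nt` non-threonine sequences
#' over 8 code columns plus an Asp anchor column. "Planted" cells draw the
#' planted residue with the stated per-category frequency and otherwise draw
#' from the background distribution excluding that residue (so the empirical
#' planted frequency is unbiased); unplanted cells draw from the background.
#' The anchor column draws Asp with the per-category fractions, which default
#' to the study dataset's filter outcome (38/39 in T, 1196/1507 in NT).
#'
#' @param n_t,n_nt Category sizes (>= 1).
#' @param planted Tibble/data frame with columns `position` (code index
#'   1..8), `residue`, `f_t`, `f_nt`; may be empty.
#' @param background Named probability vector over residue symbols (default
#'   uniform over the 20 proteinogenic amino acids).
#' @param anchor_asp Length-2 named vector `c(T = ., NT = .)` of Asp
#'   fractions at the anchor column.
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return A `labeled_alignment` of 9 columns (code columns 1..8, anchor 9),
#'   with the matching [code_positions()] attached as attribute `code`.
#' @export
gen_sequence_set <- function(n_t, n_nt, planted = NULL, background = NULL,
                             anchor_asp = c(T = 38 / 39, NT = 1196 / 1507),
                             seed = 1L) {
  stopifnot(n_t >= 1, n_nt >= 1)
  aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  if (is.null(background)) background <- stats::setNames(rep(1 / 20, 20), aa20)
  background <- background / sum(background)
  if (is.null(planted)) {
    planted <- tibble::tibble(position = integer(), residue = character(),
                              f_t = numeric(), f_nt = numeric())
  }
  planted <- tibble::as_tibble(planted)
  if (nrow(planted) > 0) {
    stopifnot(all(c("position", "residue", "f_t", "f_nt") %in% names(planted)))
    if (any(planted$f_t < 0 | planted$f_t > 1 |
              planted$f_nt < 0 | planted$f_nt > 1)) {
      stop("planted frequencies must lie in [0, 1]", call. = FALSE)
    }
    if (any(planted$position < 1 | planted$position > 8)) {
      stop("planted positions must be code indices 1..8", call. = FALSE)
    }
  }
  withr::with_seed(seed, {
    draw_col <- function(n, planted_res = NULL, f = NULL) {
      if (is.null(planted_res)) {
        sample(names(background), n, replace = TRUE, prob = background)
      } else {
        hit <- stats::runif(n) < f
        bg <- background[names(background) != planted_res]
        out <- character(n)
        out[hit] <- planted_res
        if (any(!hit)) out[!hit] <- sample(names(bg), sum(!hit),
                                           replace = TRUE, prob = bg)
        out
      }
    }
    gen_cat <- function(n, cat) {
      cols <- lapply(1:8, function(p) {
        row <- planted[planted$position == p, , drop = FALSE]
        if (nrow(row) == 1) {
          draw_col(n, row$residue,
                   if (cat == "T") row$f_t else row$f_nt)
        } else draw_col(n)
      })
      anchor <- draw_col(n, "D", anchor_asp[[cat]])
      apply(cbind(do.call(cbind, cols), anchor), 1, paste0, collapse = "")
    }
    seqs <- c(gen_cat(n_t, "T"), gen_cat(n_nt, "NT"))
  })
  rec <- tibble::tibble(
    id = c(sprintf("T_%04d", seq_len(n_t)), sprintf("NT_%04d", seq_len(n_nt))),
    seq = seqs
  )
  lab <- tibble::tibble(id = rec$id,
                        category = rep(c("T", "NT"), c(n_t, n_nt)))
  out <- labeled_alignment(rec, lab)
  attr(out, "code") <- code_positions(1:8, 9)
  out
}

# mean-1 multiplicative lognormal noise at a given CV
noise_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
}

#' Generate a synthetic peak list
#'
#' Seeded spectrum generator with the statistical structure the annotation
#' and quantification stages assume: for each species and charge, an isotopic
#' envelope of `K + 1` peaks at `mono + k * 1.00335 / z` whose relative
#' intensities follow Poisson weights with mean `lambda * M / 1000` (a
#' carbon-count proxy; the pipeline sums envelopes and never fits their
#' shape), scaled so the envelope total equals the species abundance at zero
#' noise; plus, for singly-charged species, a retro-Diels-Alder companion
#' envelope at `rda_fraction` of the main abundance. Peak m/z are jittered
#' with Gaussian noise of sd `mz_sd`; intensities get mean-1 multiplicative
#' lognormal noise of the given CV.
#'
#' @param species Tibble with columns `label`, `abundance`, and either
#'   `mass` (neutral monoisotopic Da) or `variant` (list of `pvd_variant`).
#' @param charges Integer charges (default 1, the MALDI case).
#' @param K Isotopologues beyond the mono peak.
#' @param lambda Envelope parameter per 1000 Da (default 0.65).
#' @param rda_fraction Companion envelope abundance as a fraction of the main.
#' @param mz_sd Gaussian m/z jitter sd in Da.
#' @param intensity_cv Multiplicative intensity noise CV.
#' @param mode Instrument mode recorded on the peak list.
#' @param rda_loss Neutral RDA loss in Da.
#' @param seed Integer seed.
#' @param registry Registry (used when `species$variant` is given).
#' @return A `peaklist`; species whose envelopes overlap within `3 * mz_sd`
#'   are flagged in attribute `overlaps`. Attribute `truth` holds the
#'   per-species mono m/z table.
#' @export
gen_peaklist <- function(species, charges = 1L, K = 4L, lambda = 0.65,
                         rda_fraction = 0, mz_sd = 0, intensity_cv = 0,
                         mode = c("MALDI", "ESI"), rda_loss = 303.13,
                         seed = 1L, registry = default_registry()) {
  mode <- match.arg(mode)
  species <- tibble::as_tibble(species)
  stopifnot(all(c("label", "abundance") %in% names(species)),
            all(species$abundance > 0), mz_sd >= 0, intensity_cv >= 0,
            rda_fraction >= 0, rda_fraction <= 1, K >= 0)
  if (!"mass" %in% names(species)) {
    stopifnot("variant" %in% names(species))
    species$mass <- vapply(species$variant, neutral_mass, numeric(1),
                           registry = registry)
  }
  const <- mass_constants(rda_loss)
  rows <- list(); truth <- list()
  for (i in seq_len(nrow(species))) {
    M <- species$mass[i]
    w <- stats::dpois(0:K, lambda * M / 1000)
    w <- w / sum(w)
    for (z in sort(unique(as.integer(charges)))) {
      mono <- ion_mz(M, z)
      truth[[length(truth) + 1L]] <- tibble::tibble(
        label = species$label[i], z = z, mono_mz = mono)
      roots <- c(main = mono,
                 if (rda_fraction > 0 && z == 1L) c(rda = mono - rda_loss))
      scale <- c(main = species$abundance[i],
                 if (rda_fraction > 0 && z == 1L)
                   c(rda = species$abundance[i] * rda_fraction))
      for (r in names(roots)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          mz = roots[[r]] + (0:K) * const$isotope_spacing / z,
          intensity = scale[[r]] * w)
      }
    }
  }
  d <- dplyr::bind_rows(rows)
  d <- withr::with_seed(seed, {
    d$mz <- d$mz + stats::rnorm(nrow(d), 0, mz_sd)
    d$intensity <- d$intensity * noise_factor(nrow(d), intensity_cv)
    d
  })
  out <- peaklist(d$mz, d$intensity, mode = mode, label = "simulated")
  truth <- dplyr::bind_rows(truth)
  attr(out, "truth") <- truth
  # species whose mono positions collide within jitter reach
  if (nrow(truth) > 1) {
    dm <- abs(outer(truth$mono_mz, truth$mono_mz, `-`))
    hit <- which(dm < max(3 * mz_sd, 1e-9) & upper.tri(dm), arr.ind = TRUE)
    if (nrow(hit) > 0) {
      attr(out, "overlaps") <- tibble::tibble(a = truth$label[hit[, 1]],
                                              b = truth$label[hit[, 2]])
    }
  }
  out
}

#' Generate a titration calibration series
#'
#' One synthetic peak list per known mixing ratio, with species A's abundance
#' equal to `ratio * response_factor * abundance_b` — so a response-factor
#' fit of the measured intensity ratios on the known ratios recovers
#' `response_factor` as the slope. Per-ratio seeds are derived
#' deterministically from the master seed.
#'
#' @param ratios Known concentration ratios (> 0, nonempty).
#' @param response_factor True MS response factor of A relative to B.
#' @param mass_a,mass_b Neutral monoisotopic masses of the two species.
#' @param abundance_b Abundance of the reference species B.
#' @param K,lambda,rda_fraction,mz_sd,intensity_cv,rda_loss See
#'   [gen_peaklist()].
#' @param seed Master integer seed.
#' @return Tibble `known_ratio`, `peaklist` (list column).
#' @export
gen_titration <- function(ratios, response_factor, mass_a, mass_b,
                          abundance_b = 1000, K = 4L, lambda = 0.65,
                          rda_fraction = 0.3, mz_sd = 0, intensity_cv = 0,
                          rda_loss = 303.13, seed = 1L) {
  if (length(ratios) == 0) stop("empty ratio list", call. = FALSE)
  stopifnot(all(ratios > 0), response_factor > 0)
  pls <- purrr::map(seq_along(ratios), function(i) {
    gen_peaklist(
      tibble::tibble(label = c("A", "B"),
                     mass = c(mass_a, mass_b),
                     abundance = c(ratios[i] * response_factor * abundance_b,
                                   abundance_b)),
      charges = 1L, K = K, lambda = lambda, rda_fraction = rda_fraction,
      mz_sd = mz_sd, intensity_cv = intensity_cv, mode = "MALDI",
      rda_loss = rda_loss, seed = (seed %% 100000L) * 10000L + i * 13L)
  })
  tibble::tibble(known_ratio = ratios, peaklist = pls)
}
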