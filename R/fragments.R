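# admissible fragment indices for a scaffold; the macrocycle is atomic: no
# fragment requiring two backbone cleavages is emitted
fragment_bounds <- function(scaffold) {
  n_res <- length(scaffold$residues)
  if (is.null(scaffold$cycle_span)) {
    list(y = c(1L, n_res - 1L), b = c(1L, n_res - 1L), cyclic = FALSE,
         cycle_size = 0L, cycle_start = NA_integer_)
  } else {
    cs <- scaffold$cycle_span
    list(y = c(cs[2] - cs[1] + 1L, n_res - 1L), b = c(1L, cs[1] - 1L),
         cyclic = TRUE, cycle_size = cs[2] - cs[1] + 1L, cycle_start = cs[1])
  }
}

fragment_row <- function(series, n, z, mz, span, scaffold) {
  contains_cycle <- !is.null(scaffold$cycle_span) &&
    span[1] <= scaffold$cycle_span[1] && span[2] >= scaffold$cycle_span[2]
  tibble::tibble(series = series, n = as.integer(n), z = as.integer(z),
                 mz = unname(mz), span_start = as.integer(span[1]),
                 span_end = as.integer(span[2]),
                 contains_cycle = contains_cycle,
                 low_ce_only = contains_cycle)
}

#' y-fragment ion of a variant peptide
#'
#' C-terminal fragment of the last `n` residues:
#' `mz = (sum of the last n residue masses + z * proton) / z`, with no
#' terminal-water term because the C-terminus is consumed by the macrolactam
#' closure. For a cyclized scaffold, y-ions smaller than the cycle are not
#' generated — a single backbone cleavage cannot open the ring — so
#' `cycle_size <= n <= n_residues - 1`. Fragments containing the intact ring
#' are flagged `low_ce_only` (in the study they were detected at 30–35 eV
#' collision energy only). For a linear scaffold the free C-terminal water
#' (18.01056 Da) is restored.
#'
#' @param variant A `pvd_variant` (or scaffold, taken as identity).
#' @param n Fragment index (number of C-terminal residues).
#' @param z Positive integer charge.
#' @param registry Registry tibble.
#' @return One-row tibble: `series`, `n`, `z`, `mz`, `span_start`, `span_end`,
#'   `contains_cycle`, `low_ce_only`.
#' @examples
#' y_ion(pvd_variant(pvd_scaffold()), 4)  # native y4, m/z ~489.267
#' @export
y_ion <- function(variant, n, z = 1L, registry = default_registry()) {
  if (inherits(variant, "pvd_scaffold")) variant <- pvd_variant(variant, registry = registry)
  stopifnot(inherits(variant, "pvd_variant"), z >= 1)
  sc <- variant$scaffold
  b <- fragment_bounds(sc)
  n_res <- length(sc$residues)
  if (n >= n_res) {
    stop("y", n, " is the full peptide (precursor), not a fragment", call. = FALSE)
  }
  if (n < b$y[1]) {
    stop("y", n, " would require opening the macrocycle (positions ",
         sc$cycle_span[1], "..", sc$cycle_span[2],
         "); a single backbone cleavage cannot open the ring", call. = FALSE)
  }
  res <- variant_residues(variant)
  span <- c(n_res - n + 1L, n_res)
  m <- sum(block_mass(res[span[1]:span[2]], registry))
  if (!b$cyclic) m <- m + mass_constants()$water
  fragment_row("y", n, z, (m + z * mass_constants()$proton) / z, span, sc)
}

#' b-fragment ion of a variant peptide
#'
#' N-terminal fragment: the chromophore-acyl unit plus the first `n` residues,
#' `mz = (mass(chromophore) + sum of residue masses 1..n + z * proton) / z`.
#' For a cyclized scaffold b-ions cutting inside the ring are not generated,
#' so `1 <= n <= cycle_start - 1`.
#'
#' @inheritParams y_ion
#' @return One-row fragment tibble (see [y_ion()]).
#' @export
b_ion <- function(variant, n, z = 1L, registry = default_registry()) {
  if (inherits(variant, "pvd_scaffold")) variant <- pvd_variant(variant, registry = registry)
  stopifnot(inherits(variant, "pvd_variant"), z >= 1)
  sc <- variant$scaffold
  b <- fragment_bounds(sc)
  if (n < 1) stop("b-ion index must be >= 1", call. = FALSE)
  if (n > b$b[2]) {
    stop(if (b$cyclic) paste0("b", n, " would cut inside the macrocycle (allowed: b1..b",
                              b$b[2], ")")
         else paste0("b", n, " exceeds the fragment range (allowed: b1..b", b$b[2], ")"),
         call. = FALSE)
  }
  res <- variant_residues(variant)
  m <- block_mass(sc$chromophore, registry) + sum(block_mass(res[1:n], registry))
  fragment_row("b", n, z, (m + z * mass_constants()$proton) / z, c(1L, n), sc)
}

#' Full b/y fragment table of a variant
#'
#' All admissible b- and y-ions at the requested charges, sorted by m/z.
#' Only the b and y series are generated (the series the study's MS/MS
#' annotation uses); the macrocycle is treated as an uncleavable unit.
#'
#' @param variant A `pvd_variant` (or scaffold, taken as identity).
#' @param charges Integer charges.
#' @param registry Registry tibble.
#' @return Tibble of fragment rows (see [y_ion()]), sorted by `mz`.
#' @examples
#' fragment_table(pvd_variant(pvd_scaffold()))
#' @export
fragment_table <- function(variant, charges = 1L, registry = default_registry()) {
  if (inherits(variant, "pvd_scaffold")) variant <- pvd_variant(variant, registry = registry)
  stopifnot(inherits(variant, "pvd_variant"))
  b <- fragment_bounds(variant$scaffold)
  charges <- sort(unique(as.integer(charges)))
  rows <- list()
  for (z in charges) {
    if (b$b[2] >= b$b[1]) {
      for (n in seq(b$b[1], b$b[2]))
        rows[[length(rows) + 1L]] <- b_ion(variant, n, z, registry)
    }
    if (b$y[2] >= b$y[1]) {
      for (n in seq(b$y[1], b$y[2]))
        rows[[length(rows) + 1L]] <- y_ion(variant, n, z, registry)
    }
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$mz)
}

#' Write a fragment table as TSV
#'
#' Columns `series`, `n`, `z`, `mz` (3 decimals in the file; matching always
#' uses tolerances, never rounding), `span_start`, `span_end`, `low_ce_only`.
#'
#' @param fragments Fragment tibble from [fragment_table()].
#' @param path Output path.
#' @export
write_fragment_tsv <- function(fragments, path) {
  out <- fragments
  out$mz <- sprintf("%.3f", out$mz)
  readr::write_tsv(out, path)
  invisible(path)
}
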