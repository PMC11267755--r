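#' Pyoverdine peptide scaffold
#'
#' A scaffold is the chromophore-acyl unit plus an ordered list of residue
#' blocks (1-based, N to C) and an optional C-terminal macrocycle span. The
#' PAO1 pyoverdine default is Ser-Arg-Ser-fOHOrn-Lys-fOHOrn-Thr-Thr with the
#' macrolactam closed from the Lys5 side chain to the Thr8 C-terminus
#' (cycle span 5..8).
#'
#' @param residues Character vector of residue block ids, positions 1..n.
#' @param chromophore Chromophore-acyl block id.
#' @param cycle_span Integer length-2 inclusive 1-based range closed
#'   side-chain-to-C-terminus, or `NULL` for a linear scaffold. Must end at
#'   the last residue.
#' @param side_chain_form `"succinate"` or `"succinamide"`; recorded metadata,
#'   the mass difference is carried by the chromophore block itself.
#' @param registry Registry used to validate the block ids.
#' @return An object of class `pvd_scaffold`.
#' @examples
#' pvd_scaffold()
#' @export
pvd_scaffold <- function(residues = c("Ser", "Arg", "Ser", "fOHOrn",
                                      "Lys", "fOHOrn", "Thr", "Thr"),
                         chromophore = if (side_chain_form == "succinate")
                           "ChrSuc" else "ChrSucA",
                         cycle_span = c(5L, 8L),
                         side_chain_form = c("succinate", "succinamide"),
                         registry = default_registry()) {
  side_chain_form <- match.arg(side_chain_form)
  stopifnot(is.character(residues), length(residues) >= 1)
  rrole <- registry$role[match(residues, registry$id)]
  if (anyNA(rrole)) {
    stop("unknown residue block id: ",
         paste(residues[is.na(rrole)], collapse = ", "), call. = FALSE)
  }
  if (any(rrole != "residue")) stop("scaffold residues must have role 'residue'",
                                    call. = FALSE)
  crole <- registry$role[match(chromophore, registry$id)]
  if (is.na(crole) || crole != "chromophore_acyl") {
    stop("chromophore block must exist with role 'chromophore_acyl'",
         call. = FALSE)
  }
  n <- length(residues)
  if (!is.null(cycle_span)) {
    cycle_span <- as.integer(cycle_span)
    stopifnot(length(cycle_span) == 2, cycle_span[1] >= 1,
              cycle_span[1] <= cycle_span[2])
    if (cycle_span[2] != n) {
      stop("cycle_span must end at the last residue (", n, ")", call. = FALSE)
    }
  }
  structure(
    list(residues = residues, chromophore = chromophore,
         cycle_span = cycle_span, side_chain_form = side_chain_form),
    class = "pvd_scaffold"
  )
}

#' @export
print.pvd_scaffold <- function(x, ...) {
  cat("<pvd_scaffold> ", x$chromophore, "-[",
      paste(x$residues, collapse = "-"), "]",
      if (!is.null(x$cycle_span))
        paste0("  cycle ", x$cycle_span[1], "..", x$cycle_span[2])
      else "  linear",
      "  (", x$side_chain_form, ")\n", sep = "")
  invisible(x)
}

#' Read a scaffold definition from a YAML config
#'
#' Keys: `residues` (list of block ids), `chromophore`, `cycle_span`
#' (two integers or absent for linear), `side_chain_form`. A packaged example
#' is at `system.file("extdata", "pao1_scaffold.yaml", package = "pvdms")`.
#'
#' @param path YAML file path.
#' @param registry Registry used for validation.
#' @return A `pvd_scaffold`.
#' @export
read_scaffold <- function(path, registry = default_registry()) {
  if (!file.exists(path)) stop("scaffold config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  pvd_scaffold(
    residues = as.character(unlist(cfg$residues)),
    chromophore = cfg$chromophore %||%
      if ((cfg$side_chain_form %||% "succinate") == "succinate") "ChrSuc" else "ChrSucA",
    cycle_span = if (is.null(cfg$cycle_span)) NULL else as.integer(unlist(cfg$cycle_span)),
    side_chain_form = cfg$side_chain_form %||% "succinate",
    registry = registry
  )
}

#' Define a variant peptide
#'
#' A variant is a scaffold plus a position -> block substitution map.
#' Substituting a position with its original block is the identity variant.
#'
#' @param scaffold A `pvd_scaffold`.
#' @param substitutions Named character vector or list mapping 1-based
#'   positions (names) to block ids, e.g. `c("8" = "Ser")`. Empty for the
#'   identity variant.
#' @param label Optional label; autogenerated from the substitutions if `NULL`.
#' @param registry Registry used for validation.
#' @return An object of class `pvd_variant`.
#' @examples
#' pvd_variant(pvd_scaffold(), c("8" = "Ser"))
#' @export
pvd_variant <- function(scaffold, substitutions = character(), label = NULL,
                        registry = default_registry()) {
  stopifnot(inherits(scaffold, "pvd_scaffold"))
  subs <- unlist(substitutions)
  if (length(subs) > 0) {
    pos <- as.integer(names(subs))
    if (anyNA(pos) || any(pos < 1) || any(pos > length(scaffold$residues))) {
      stop("substituted positions must exist in the scaffold", call. = FALSE)
    }
    if (anyDuplicated(pos)) stop("duplicate substituted position", call. = FALSE)
    block_mass(as.character(subs), registry)  # errors on unresolvable ids
    subs <- stats::setNames(as.character(subs), pos)
    subs <- subs[order(pos)]
  } else {
    subs <- stats::setNames(character(0), integer(0))
  }
  if (is.null(label)) {
    label <- if (length(subs) == 0) "native" else
      paste(paste0(names(subs), unname(subs)), collapse = "+")
  }
  structure(list(scaffold = scaffold, substitutions = subs, label = label),
            class = "pvd_variant")
}

#' @export
print.pvd_variant <- function(x, ...) {
  cat("<pvd_variant> ", x$label, "\n", sep = "")
  print(x$scaffold)
  invisible(x)
}

# residue ids of a variant after applying its substitution map
variant_residues <- function(variant) {
  res <- variant$scaffold$residues
  if (length(variant$substitutions) > 0) {
    res[as.integer(names(variant$substitutions))] <- unname(variant$substitutions)
  }
  res
}

#' Neutral monoisotopic mass of a variant peptide
#'
#' `M = mass(chromophore-acyl) + sum(residue masses after substitution)`.
#' There is no terminal-water term: the macrolactam closure and the N-terminal
#' chromophore acylation consume both termini, so the condensation waters
#' cancel exactly. (For a linear scaffold the same convention is kept for the
#' precursor; the free C-terminal water reappears only in its y-ions, see
#' [y_ion()].)
#'
#' @param variant A `pvd_variant` (or a bare `pvd_scaffold`, taken as its
#'   identity variant).
#' @param registry Registry tibble.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' neutral_mass(pvd_variant(pvd_scaffold()))  # native PVD, ~1333.59
#' @export
neutral_mass <- function(variant, registry = default_registry()) {
  if (inherits(variant, "pvd_scaffold")) variant <- pvd_variant(variant, registry = registry)
  stopifnot(inherits(variant, "pvd_variant"))
  unname(sum(block_mass(variant_residues(variant), registry)) +
           block_mass(variant$scaffold$chromophore, registry))
}

#' Enumerate candidate variants over positions and an alphabet
#'
#' All combinations of the alphabet over the given positions (including the
#' identity). Variants sharing a neutral mass (isobaric combinations, e.g. the
#' two single-Ser substitutions of the Thr7-Thr8 pair) are flagged as one mass
#' group.
#'
#' @param scaffold A `pvd_scaffold`.
#' @param positions Integer vector of 1-based positions to vary (possibly
#'   empty: only the identity is returned).
#' @param alphabet Character vector of residue block ids to substitute.
#' @param registry Registry tibble.
#' @return A tibble with columns `label`, `variant` (list of `pvd_variant`),
#'   `neutral_mass`, `mass_group` (integer id shared by isobaric variants).
#' @examples
#' enumerate_variants(pvd_scaffold(), c(7, 8), c("Thr", "Ser"))
#' @export
enumerate_variants <- function(scaffold, positions, alphabet,
                               registry = default_registry()) {
  stopifnot(inherits(scaffold, "pvd_scaffold"))
  positions <- sort(unique(as.integer(positions)))
  if (length(alphabet) == 0) stop("alphabet must be non-empty", call. = FALSE)
  if (length(positions) > 0 &&
      (min(positions) < 1 || max(positions) > length(scaffold$residues))) {
    stop("positions must lie within the scaffold", call. = FALSE)
  }
  block_mass(alphabet, registry)
  combos <- if (length(positions) == 0) {
    list(character(0))
  } else {
    grid <- do.call(expand.grid,
                    c(stats::setNames(rep(list(alphabet), length(positions)),
                                      positions),
                      list(stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)))
    lapply(seq_len(nrow(grid)), function(i) {
      v <- as.character(grid[i, , drop = TRUE])
      names(v) <- positions
      # drop identity entries so equivalent substitution maps collapse
      keep <- v != scaffold$residues[positions]
      v[keep]
    })
  }
  combos <- combos[!duplicated(vapply(combos, function(v)
    paste(names(v), v, sep = ":", collapse = ","), character(1)))]
  variants <- lapply(combos, function(v)
    pvd_variant(scaffold, v, registry = registry))
  mass <- vapply(variants, neutral_mass, numeric(1), registry = registry)
  out <- tibble::tibble(
    label = vapply(variants, `[[`, character(1), "label"),
    variant = variants,
    neutral_mass = mass
  )
  out <- out[order(out$neutral_mass, out$label), ]
  out$mass_group <- cumsum(c(TRUE, diff(out$neutral_mass) > 1e-6))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
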