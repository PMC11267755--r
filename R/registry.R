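# residue formulas: amino acid minus water, the additive unit of peptide mass
# arithmetic. Leu and Ile are isobaric and kept as one entry, as MS cannot
# distinguish them. Chromophore-acyl blocks are the dihydroxyquinoline
# chromophore as an in-chain unit (acid condensed onto residue 1) carrying the
# succinyl / succinamoyl side chain; the two forms differ by 0.98402 Da
# (acid vs amide).
.registry_source <- function() {
  tribble_ <- tibble::tribble
  tribble_(
    ~id,        ~name,                                ~role,              ~class,             ~formula,
    "Gly",      "glycine",                            "residue",          "proteinogenic",    "C2H3NO",
    "Ala",      "alanine",                            "residue",          "proteinogenic",    "C3H5NO",
    "Ser",      "serine",                             "residue",          "proteinogenic",    "C3H5NO2",
    "Pro",      "proline",                            "residue",          "proteinogenic",    "C5H7NO",
    "Val",      "valine",                             "residue",          "proteinogenic",    "C5H9NO",
    "Thr",      "threonine",                          "residue",          "proteinogenic",    "C4H7NO2",
    "Cys",      "cysteine",                           "residue",          "proteinogenic",    "C3H5NOS",
    "Leu/Ile",  "leucine or isoleucine (isobaric)",   "residue",          "proteinogenic",    "C6H11NO",
    "Asn",      "asparagine",                         "residue",          "proteinogenic",    "C4H6N2O2",
    "Asp",      "aspartate",                          "residue",          "proteinogenic",    "C4H5NO3",
    "Gln",      "glutamine",                          "residue",          "proteinogenic",    "C5H8N2O2",
    "Lys",      "lysine",                             "residue",          "proteinogenic",    "C6H12N2O",
    "Glu",      "glutamate",                          "residue",          "proteinogenic",    "C5H7NO3",
    "Met",      "methionine",                         "residue",          "proteinogenic",    "C5H9NOS",
    "His",      "histidine",                          "residue",          "proteinogenic",    "C6H7N3O",
    "Phe",      "phenylalanine",                      "residue",          "proteinogenic",    "C9H9NO",
    "Arg",      "arginine",                           "residue",          "proteinogenic",    "C6H12N4O",
    "Tyr",      "tyrosine",                           "residue",          "proteinogenic",    "C9H9NO2",
    "Trp",      "tryptophan",                         "residue",          "proteinogenic",    "C11H10N2O",
    "Orn",      "ornithine",                          "residue",          "nonproteinogenic", "C5H10N2O",
    "Dab",      "L-2,4-diaminobutyrate",              "residue",          "nonproteinogenic", "C4H8N2O",
    "fOHOrn",   "L-N5-formyl-N5-hydroxy-ornithine",   "residue",          "nonproteinogenic", "C6H10N2O3",
    "azHA",     "4-azido-L-homoalanine",              "residue",          "nonproteinogenic", "C4H6N4O",
    "ChrSuc",   "PVD chromophore-acyl (succinate)",   "chromophore_acyl", "chromophore",      "C17H15N3O6",
    "ChrSucA",  "PVD chromophore-acyl (succinamide)", "chromophore_acyl", "chromophore",      "C17H16N4O5"
  )
}

#' Default building-block registry
#'
#' The vocabulary every mass computation draws from: monoisotopic residue
#' masses (amino acid minus water) for the 20 proteinogenic amino acids (Leu
#' and Ile as a single isobaric entry), the non-proteinogenic pyoverdine
#' residues (ornithine, Dab, fOHOrn), the clickable 4-azido-L-homoalanine, and
#' the PAO1 chromophore-acyl unit in its succinate and succinamide side-chain
#' forms.
#'
#' The mass convention: a peptide's neutral monoisotopic mass is the
#' chromophore-acyl mass plus the sum of residue masses, with no terminal
#' water term — the C-terminus is consumed by the macrolactam closure and the
#' N-terminus by the chromophore acylation, so the two condensation waters
#' cancel against the free termini exactly.
#'
#' @return A tibble with columns `id`, `name`, `role` (`residue` or
#'   `chromophore_acyl`), `class` (`proteinogenic`, `nonproteinogenic`,
#'   `chromophore`), `formula`, `mono_mass` (Da), `nominal_mass` (integer Da).
#' @examples
#' reg <- default_registry()
#' reg[reg$id == "Thr", "mono_mass"]
#' @export
default_registry <- function() {
  reg <- .registry_source()
  reg$mono_mass <- vapply(reg$formula, formula_mass, numeric(1), USE.NAMES = FALSE)
  reg$nominal_mass <- as.integer(round(reg$mono_mass))
  validate_registry(reg)
}

#' Validate a building-block registry
#'
#' Checks ids are unique, masses positive, formulas (when present) agree with
#' `mono_mass` within 1e-4 Da, and `nominal_mass` is the rounded mono mass.
#'
#' @param registry A registry tibble (see [default_registry()]).
#' @return The validated registry, invisibly classed `pvd_registry`.
#' @export
validate_registry <- function(registry) {
  stopifnot(is.data.frame(registry),
            all(c("id", "role", "mono_mass") %in% names(registry)))
  if (anyDuplicated(registry$id)) {
    stop("duplicate block id: ",
         paste(unique(registry$id[duplicated(registry$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(registry$mono_mass <= 0)) stop("mono_mass must be positive", call. = FALSE)
  if (!all(registry$role %in% c("residue", "chromophore_acyl"))) {
    stop("role must be 'residue' or 'chromophore_acyl'", call. = FALSE)
  }
  if ("formula" %in% names(registry)) {
    has_f <- !is.na(registry$formula) & nzchar(registry$formula)
    fmass <- vapply(registry$formula[has_f], formula_mass, numeric(1))
    dev <- abs(fmass - registry$mono_mass[has_f])
    if (any(dev >= 1e-4)) {
      stop("mono_mass disagrees with formula for: ",
           paste(registry$id[has_f][dev >= 1e-4], collapse = ", "),
           call. = FALSE)
    }
  }
  if (!"nominal_mass" %in% names(registry)) {
    registry$nominal_mass <- as.integer(round(registry$mono_mass))
  } else if (any(registry$nominal_mass != as.integer(round(registry$mono_mass)))) {
    stop("nominal_mass must be mono_mass rounded to nearest integer", call. = FALSE)
  }
  class(registry) <- unique(c("pvd_registry", class(registry)))
  registry
}

#' Look up monoisotopic block masses
#'
#' @param ids Character vector of block ids.
#' @param registry Registry tibble.
#' @return Numeric vector of monoisotopic masses (Da), named by id.
#' @export
block_mass <- function(ids, registry = default_registry()) {
  idx <- match(ids, registry$id)
  if (anyNA(idx)) {
    stop("unknown block id: ", paste(ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(registry$mono_mass[idx], ids)
}

#' Blocks isobaric to a block
#'
#' Two blocks are isobaric when their monoisotopic masses agree within `tol`.
#'
#' @param id Block id.
#' @param registry Registry tibble.
#' @param tol Mass agreement tolerance in Da.
#' @return Character vector of ids (including `id` itself).
#' @export
isobars <- function(id, registry = default_registry(), tol = 1e-4) {
  m <- block_mass(id, registry)
  registry$id[registry$role == "residue" &
                abs(registry$mono_mass - m) < tol]
}

#' Read / write a registry as TSV
#'
#' The external interface for building-block registries: a TSV with columns
#' `id`, `name`, `role`, `formula`, `mono_mass` (and optionally `class`,
#' `nominal_mass`). A packaged default lives at
#' `system.file("extdata", "building_blocks.tsv", package = "pvdms")`.
#'
#' @param path File path.
#' @return `read_registry()` returns a validated registry tibble.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  reg <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  validate_registry(reg)
}

#' @rdname read_registry
#' @param registry Registry tibble to write.
#' @export
write_registry <- function(registry, path) {
  readr::write_tsv(as.data.frame(registry), path)
  invisible(path)
}
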