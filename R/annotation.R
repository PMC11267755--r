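#' Match observed peaks to candidate ions
#'
#' Greedy nearest-mass assignment: among all peak/candidate pairs with
#' absolute mass error within `tol`, repeatedly commit the pair with the
#' smallest error (ties broken by lower candidate m/z, then lower peak m/z),
#' removing both from play. Each peak and each candidate is assigned at most
#' once; the procedure is deterministic. A peak equidistant from two available
#' candidates is assigned by the tie-break and flagged ambiguous.
#'
#' @param obs A `peaklist` (or tibble with `mz`, `intensity`).
#' @param candidates Tibble of candidate ions with an `mz` column; other
#'   columns (e.g. `label`, `series`, `z`) are carried into the assignments.
#' @param tol Matching tolerance in Da (default from the peak list's mode).
#' @return An object of class `match_result`: list with `assignments`
#'   (tibble `peak_mz`, `peak_intensity`, candidate columns, `error`,
#'   `ambiguous`), `unmatched_peaks`, `unmatched_candidates`, `tol`.
#' @export
match_peaks <- function(obs, candidates,
                        tol = default_tolerance(peaklist_mode(obs))) {
  stopifnot(is.data.frame(obs), tol > 0)
  candidates <- tibble::as_tibble(candidates)
  if (nrow(candidates) > 0) stopifnot("mz" %in% names(candidates))
  n_p <- nrow(obs); n_c <- nrow(candidates)
  pairs <- if (n_p > 0 && n_c > 0) {
    err <- outer(obs$mz, candidates$mz, `-`)
    idx <- which(abs(err) <= tol, arr.ind = TRUE)
    tibble::tibble(p = idx[, 1], c = idx[, 2],
                   error = err[idx], abs_error = abs(err[idx]),
                   cand_mz = candidates$mz[idx[, 2]], peak_mz = obs$mz[idx[, 1]])
  } else tibble::tibble(p = integer(), c = integer(), error = numeric(),
                        abs_error = numeric(), cand_mz = numeric(),
                        peak_mz = numeric())
  pairs <- dplyr::arrange(pairs, .data$abs_error, .data$cand_mz, .data$peak_mz)
  taken_p <- logical(n_p); taken_c <- logical(n_c)
  keep <- integer(); ambiguous <- logical()
  for (i in seq_len(nrow(pairs))) {
    pi <- pairs$p[i]; ci <- pairs$c[i]
    if (taken_p[pi] || taken_c[ci]) next
    # ambiguous when another still-available candidate sits at the same distance
    rivals <- pairs$abs_error[pairs$p == pi & pairs$c != ci & !taken_c[pairs$c]]
    ambiguous <- c(ambiguous, any(abs(rivals - pairs$abs_error[i]) < 1e-9))
    keep <- c(keep, i)
    taken_p[pi] <- TRUE; taken_c[ci] <- TRUE
  }
  asg <- pairs[keep, , drop = FALSE]
  assignments <- dplyr::bind_cols(
    tibble::tibble(peak_mz = obs$mz[asg$p],
                   peak_intensity = obs$intensity[asg$p]),
    candidates[asg$c, , drop = FALSE],
    tibble::tibble(error = asg$error, ambiguous = ambiguous)
  )
  assignments <- dplyr::arrange(assignments, .data$peak_mz)
  structure(list(
    assignments = assignments,
    unmatched_peaks = tibble::as_tibble(obs[!taken_p, c("mz", "intensity")]),
    unmatched_candidates = candidates[!taken_c, , drop = FALSE],
    tol = tol
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> ", nrow(x$assignments), " assignments (tol ",
      x$tol, " Da), ", nrow(x$unmatched_peaks), " unmatched peaks, ",
      nrow(x$unmatched_candidates), " unmatched candidates\n", sep = "")
  print(x$assignments)
  invisible(x)
}

#' @export
tidy.match_result <- function(x, ...) x$assignments

#' Infer an amino-acid substitution from a mass shift
#'
#' Returns every alphabet block whose monoisotopic residue-mass difference to
#' the reference block lies within `tol` of the observed shift. Isobaric
#' blocks are returned together. The nominal (integer) shift mirrors the
#' field's "-14 amu" phrasing; inference itself compares exact monoisotopic
#' differences. Candidates are never ranked by biological plausibility.
#'
#' @param observed_shift Observed mass shift in Da (variant minus reference).
#' @param reference Reference block id (e.g. `"Thr"`).
#' @param alphabet Candidate block ids (default: all registry residues).
#' @param tol Tolerance in Da.
#' @param registry Registry tibble.
#' @return Tibble of class `substitution_call` with columns `reference`,
#'   `candidate`, `observed_shift`, `theoretical_shift`, `nominal_shift`,
#'   `error`. Zero rows if nothing matches; the three nearest misses are then
#'   attached as attribute `nearest`.
#' @examples
#' infer_substitution(-14.01, "Thr")  # Ser
#' @export
infer_substitution <- function(observed_shift, reference,
                               alphabet = NULL, tol = 0.15,
                               registry = default_registry()) {
  if (is.null(alphabet)) alphabet <- registry$id[registry$role == "residue"]
  ref_m <- block_mass(reference, registry)
  cand_m <- block_mass(alphabet, registry)
  theo <- unname(cand_m - ref_m)
  err <- abs(theo - observed_shift)
  out <- tibble::tibble(
    reference = reference, candidate = alphabet,
    observed_shift = observed_shift, theoretical_shift = theo,
    nominal_shift = as.integer(round(theo)), error = err
  )
  hit <- out[out$error <= tol, , drop = FALSE]
  hit <- dplyr::arrange(hit, .data$error, .data$candidate)
  if (nrow(hit) == 0) {
    near <- dplyr::slice_min(out, .data$error, n = 3, with_ties = FALSE)
    attr(hit, "nearest") <- near
    message("no candidate within ", tol, " Da of shift ", observed_shift,
            "; nearest: ",
            paste0(near$candidate, " (", sprintf("%+.3f", near$theoretical_shift),
                   ")", collapse = ", "))
  }
  class(hit) <- unique(c("substitution_call", class(hit)))
  hit
}

#' Localize a substitution from MS/MS fragment shift patterns
#'
#' Implements the study's localization argument: a substitution lies in every
#' shifted fragment's span and in no unshifted fragment's span. The window is
#' the intersection of the spans of all shifted fragments minus the union of
#' the spans of all unshifted fragments, further intersected with the
#' positions whose reference residue can yield the observed shift under the
#' given alphabet. For the native pattern (y4 and y7 shifted by -14, b-series
#' unshifted) the window is the two in-ring threonines, positions 7 and 8.
#'
#' A shifted fragment nested inside an unshifted one is mutually inconsistent;
#' the call is then flagged ambiguous and both candidate windows (shifted-only
#' and the full rule) are reported rather than silently guessing.
#'
#' @param ref_table Fragment table of the reference peptide
#'   ([fragment_table()] output).
#' @param obs_shifts Tibble with columns `series`, `n`, `shift` (observed m/z
#'   shift of that fragment, in Da; include unshifted fragments with shift ~0).
#' @param reference The reference `pvd_variant` (used for per-position
#'   reference residues).
#' @param alphabet Candidate block ids for the shift (default: proteinogenic
#'   residues plus azHA).
#' @param tol Shift significance / matching tolerance in Da. The default is
#'   the ESI tolerance (0.02 Da) because the fragment shifts come from ESI
#'   MS/MS; at MALDI-scale tolerances near-isobaric decoys (Lys->Asn at
#'   -14.052 vs Thr->Ser at -14.016) become indistinguishable.
#' @param registry Registry tibble.
#' @return List of class `localization_call`: `window` (positions whose
#'   reference residue can also yield the shift), `window_spatial` (the pure
#'   set-arithmetic window before the chemistry filter), `candidates` (tibble
#'   `position`, `reference`, `candidate`, `theoretical_shift`,
#'   `nominal_shift`), `observed_shift`, `nominal_shift`, `ambiguous`,
#'   `windows` (list, when ambiguous), `identity` (TRUE when no fragment is
#'   shifted).
#' @export
localize_from_msms <- function(ref_table, obs_shifts, reference,
                               alphabet = NULL, tol = 0.02,
                               registry = default_registry()) {
  stopifnot(is.data.frame(obs_shifts),
            all(c("series", "n", "shift") %in% names(obs_shifts)))
  if (is.null(alphabet)) {
    alphabet <- registry$id[registry$role == "residue" &
                              (registry$class == "proteinogenic" |
                                 registry$id == "azHA")]
  }
  res <- variant_residues(reference)
  n_res <- length(res)
  d <- dplyr::inner_join(obs_shifts, ref_table, by = c("series", "n"))
  if (nrow(d) < nrow(obs_shifts)) {
    miss <- dplyr::anti_join(obs_shifts, ref_table, by = c("series", "n"))
    stop("observed shifts refer to fragments absent from the reference table: ",
         paste0(miss$series, miss$n, collapse = ", "), call. = FALSE)
  }
  d$is_shifted <- abs(d$shift) > tol
  spans <- function(rows) purrr::map2(rows$span_start, rows$span_end, seq)
  shifted <- d[d$is_shifted, , drop = FALSE]
  unshifted <- d[!d$is_shifted, , drop = FALSE]

  if (nrow(shifted) == 0) {
    out <- list(window = seq_len(n_res), window_spatial = seq_len(n_res),
                candidates = tibble::tibble(),
                observed_shift = 0, nominal_shift = 0L, ambiguous = FALSE,
                windows = NULL, identity = TRUE)
    class(out) <- "localization_call"
    return(out)
  }

  inter_shifted <- Reduce(intersect, spans(shifted))
  union_unshifted <- if (nrow(unshifted) > 0) unique(unlist(spans(unshifted))) else integer()
  window <- setdiff(inter_shifted, union_unshifted)

  # inconsistency: a shifted fragment nested inside an unshifted one
  nested <- any(vapply(seq_len(nrow(shifted)), function(i) {
    any(unshifted$span_start <= shifted$span_start[i] &
          unshifted$span_end >= shifted$span_end[i])
  }, logical(1)))
  ambiguous <- nested || length(window) == 0

  obs_mean <- mean(shifted$shift * shifted$z)  # neutral-scale shift
  cand <- purrr::map_dfr(window, function(p) {
    call <- infer_substitution(obs_mean, res[p], alphabet = alphabet,
                               tol = tol, registry = registry)
    if (nrow(call) == 0) return(tibble::tibble())
    tibble::tibble(position = p, reference = res[p], candidate = call$candidate,
                   theoretical_shift = call$theoretical_shift,
                   nominal_shift = call$nominal_shift)
  })
  out <- list(
    window = if (nrow(cand) == 0) integer(0) else sort(unique(cand$position)),
    window_spatial = window,
    candidates = cand,
    observed_shift = obs_mean,
    nominal_shift = as.integer(round(obs_mean)),
    ambiguous = ambiguous,
    windows = if (ambiguous) list(shifted_only = inter_shifted,
                                  full_rule = setdiff(inter_shifted, union_unshifted))
              else NULL,
    identity = FALSE
  )
  class(out) <- "localization_call"
  out
}

#' @export
print.localization_call <- function(x, ...) {
  if (x$identity) {
    cat("<localization_call> identity (no shifted fragments); window = full peptide\n")
  } else {
    cat("<localization_call> window {", paste(x$window, collapse = ","),
        "}, observed shift ", sprintf("%+.3f", x$observed_shift),
        " (nominal ", sprintf("%+d", x$nominal_shift), ")",
        if (x$ambiguous) "  [AMBIGUOUS]", "\n", sep = "")
    if (nrow(x$candidates) > 0) print(x$candidates)
  }
  invisible(x)
}

#' Annotate a spectrum with candidate pyoverdine variants
#'
#' End-to-end precursor annotation: enumerate variants over the given
#' positions and alphabet, predict their precursor ions (charges 1 and 2 by
#' default) and retro-Diels-Alder companions, match against the observed peak
#' list, and report one row per supported variant. A variant is `confirmed`
#' only when a main precursor peak matches; a variant seen only through its
#' RDA companion is reported as `companion_only` (corroborating, never
#' sufficient).
#'
#' @param obs A `peaklist`.
#' @param scaffold A `pvd_scaffold`.
#' @param positions Positions to vary.
#' @param alphabet Residue block ids to substitute.
#' @param tol Matching tolerance in Da (default from the peak list's mode).
#' @param charges Precursor charges to predict.
#' @param rda_loss Neutral RDA loss in Da.
#' @param registry Registry tibble.
#' @return Tibble: `label`, `neutral_mass`, `mass_group`, `status`
#'   (`confirmed` / `companion_only`), `n_main_matched`, `n_rda_matched`,
#'   `best_error`, `matches` (list of assignment tibbles). Variants with no
#'   matched peak are omitted.
#' @export
annotate_spectrum <- function(obs, scaffold, positions, alphabet,
                              tol = default_tolerance(peaklist_mode(obs)),
                              charges = c(1L, 2L), rda_loss = 303.13,
                              registry = default_registry()) {
  vars <- enumerate_variants(scaffold, positions, alphabet, registry)
  cand <- precursor_table(vars, charges = charges, rda = TRUE,
                          rda_loss = rda_loss, registry = registry)
  mr <- match_peaks(obs, cand, tol = tol)
  asg <- mr$assignments
  if (nrow(asg) == 0) {
    return(tibble::tibble(label = character(), neutral_mass = numeric(),
                          mass_group = integer(), status = character(),
                          n_main_matched = integer(), n_rda_matched = integer(),
                          best_error = numeric(), matches = list()))
  }
  per <- asg |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      n_main_matched = sum(!.data$is_rda_companion),
      n_rda_matched = sum(.data$is_rda_companion),
      best_error = min(abs(.data$error)),
      neutral_mass = .data$neutral_mass[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(status = ifelse(.data$n_main_matched > 0,
                                  "confirmed", "companion_only"))
  per$mass_group <- vars$mass_group[match(per$label, vars$label)]
  per$matches <- purrr::map(per$label, function(l)
    asg[asg$label == l, , drop = FALSE])
  dplyr::arrange(
    per[, c("label", "neutral_mass", "mass_group", "status",
            "n_main_matched", "n_rda_matched", "best_error", "matches")],
    .data$neutral_mass)
}

#' Write an annotation report as JSON or TSV
#'
#' The JSON report embeds the tolerances and RDA loss used so outputs are
#' self-describing; the `matches` list column is expanded per supporting peak.
#'
#' @param report Output of [annotate_spectrum()].
#' @param path Output path (`.json` or `.tsv` chosen by extension).
#' @param params Named list of run parameters echoed into the report header.
#' @export
write_annotation_report <- function(report, path, params = list()) {
  flat <- report
  flat$matches <- NULL
  if (grepl("\\.tsv$", path)) {
    readr::write_tsv(flat, path)
  } else {
    peaks <- purrr::map(report$matches, function(m)
      m[, intersect(c("peak_mz", "peak_intensity", "z", "is_rda_companion",
                      "error"), names(m))])
    jsonlite::write_json(
      list(params = params, variants = flat, supporting_peaks = peaks),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
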