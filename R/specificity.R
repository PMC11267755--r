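#' Load a category-labeled A-domain alignment
#'
#' Reads an aligned FASTA of adenylation-domain sequences and a label map
#' assigning each record to the threonine-specific (`T`) or
#' non-threonine-specific (`NT`) category, and validates that all sequences
#' have equal (aligned) length. The alignment itself is consumed, never
#' computed.
#'
#' @param fasta Path to an aligned FASTA (amino acids, gaps as `-`).
#' @param labels Either a data frame with columns `id`, `category`, or a path
#'   to a TSV with those columns.
#' @return A tibble of class `labeled_alignment` with columns `id`,
#'   `category` (factor T/NT), `seq`, and attribute `alignment_length`.
#' @export
read_labeled_alignment <- function(fasta, labels) {
  aa <- Biostrings::readAAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(aa))
  labeled_alignment(tibble::tibble(id = ids, seq = unname(as.character(aa))),
                    labels)
}

#' @rdname read_labeled_alignment
#' @param records Tibble with columns `id`, `seq`.
#' @export
labeled_alignment <- function(records, labels) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  if (is.character(labels) && length(labels) == 1) {
    labels <- readr::read_tsv(labels, show_col_types = FALSE)
  }
  stopifnot(is.data.frame(labels), all(c("id", "category") %in% names(labels)))
  if (anyDuplicated(records$id)) {
    stop("duplicate sequence id: ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "),
         call. = FALSE)
  }
  lab <- labels$category[match(records$id, labels$id)]
  if (anyNA(lab)) {
    stop("unlabeled sequence id: ",
         paste(records$id[is.na(lab)], collapse = ", "), call. = FALSE)
  }
  if (!all(lab %in% c("T", "NT"))) {
    stop("categories must be 'T' or 'NT'", call. = FALSE)
  }
  len <- nchar(records$seq)
  if (length(unique(len)) > 1) {
    ref <- as.integer(names(sort(table(len), decreasing = TRUE))[1])
    off <- records$id[len != ref][1]
    stop("alignment length mismatch: sequence '", off, "' has length ",
         len[records$id == off][1], ", expected ", ref, call. = FALSE)
  }
  out <- tibble::tibble(id = records$id,
                        category = factor(lab, levels = c("T", "NT")),
                        seq = toupper(records$seq))
  attr(out, "alignment_length") <- len[1]
  class(out) <- unique(c("labeled_alignment", class(out)))
  out
}

#' Write a labeled alignment as FASTA plus label TSV
#'
#' Inverse of [read_labeled_alignment()]: the sequences go to an aligned
#' FASTA, the id/category map to a TSV.
#'
#' @param aln A `labeled_alignment`.
#' @param fasta,labels Output paths.
#' @export
write_labeled_alignment <- function(aln, fasta, labels) {
  stopifnot(inherits(aln, "labeled_alignment"))
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(stats::setNames(aln$seq, aln$id)), fasta)
  readr::write_tsv(tibble::tibble(id = aln$id,
                                  category = as.character(aln$category)),
                   labels)
  invisible(fasta)
}

#' Specificity-code column map
#'
#' The eight 1-based alignment columns holding the specificity-conferring
#' code residues, plus the anchor column holding the conserved aspartate
#' (the Asp190-equivalent that secures the substrate alpha-amino group).
#' The mapping of code columns to PvdD residue numbers is configuration — it
#' depends entirely on the alignment supplied.
#'
#' @param code_columns Eight distinct 1-based column indices.
#' @param anchor_column The Asp anchor column (distinct from the code columns).
#' @return List of class `code_positions`.
#' @export
code_positions <- function(code_columns, anchor_column) {
  code_columns <- as.integer(code_columns)
  anchor_column <- as.integer(anchor_column)
  if (length(code_columns) != 8) stop("exactly 8 code columns required", call. = FALSE)
  cols <- c(code_columns, anchor_column)
  if (anyDuplicated(cols)) stop("code and anchor columns must be distinct", call. = FALSE)
  if (any(cols < 1)) stop("columns are 1-based", call. = FALSE)
  structure(list(code_columns = code_columns, anchor_column = anchor_column),
            class = "code_positions")
}

check_code_in_alignment <- function(aln, code) {
  alen <- attr(aln, "alignment_length")
  if (any(c(code$code_columns, code$anchor_column) > alen)) {
    stop("code/anchor columns exceed the alignment length (", alen, ")",
         call. = FALSE)
  }
}

#' Filter sequences on the conserved Asp anchor
#'
#' Retains exactly the sequences carrying aspartate at the anchor column
#' (sequences with any other residue there are removed for homogeneity, as
#' in the study's 39 T / 1507 NT to 38 T / 1196 NT reduction). Idempotent.
#'
#' @param aln A `labeled_alignment`.
#' @param code A `code_positions`.
#' @param anchor_residue Anchor residue symbol (default `"D"`).
#' @return The filtered `labeled_alignment`; retained per-category counts are
#'   attached as attribute `category_counts`. Emptying a category raises a
#'   warning, not an error.
#' @export
anchor_filter <- function(aln, code, anchor_residue = "D") {
  stopifnot(inherits(aln, "labeled_alignment"), inherits(code, "code_positions"))
  check_code_in_alignment(aln, code)
  keep <- substr(aln$seq, code$anchor_column, code$anchor_column) == anchor_residue
  out <- aln[keep, , drop = FALSE]
  attr(out, "alignment_length") <- attr(aln, "alignment_length")
  class(out) <- unique(c("labeled_alignment", class(out)))
  counts <- table(out$category)
  if (any(counts == 0)) {
    warning("anchor filter emptied category: ",
            paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  }
  attr(out, "category_counts") <- counts
  out
}

#' Per-position residue frequencies in T vs NT categories
#'
#' For each of the eight code positions and each category, the frequency of
#' every residue symbol is `count / category size`. Gaps (`-`) count as their
#' own symbol and stay in the denominator, so a gapped position dilutes
#' conservation.
#'
#' @param aln A `labeled_alignment` with both categories nonempty.
#' @param code A `code_positions`.
#' @return A tibble of class `conservation_profile`: `code_index` (1..8),
#'   `column`, `category`, `residue`, `count`, `freq`, `n` (category size).
#' @export
frequency_profile <- function(aln, code) {
  stopifnot(inherits(aln, "labeled_alignment"), inherits(code, "code_positions"))
  check_code_in_alignment(aln, code)
  sizes <- table(aln$category)
  if (any(sizes == 0)) {
    stop("both categories must be nonempty for profiling (empty: ",
         paste(names(sizes)[sizes == 0], collapse = ", "), ")", call. = FALSE)
  }
  symbols <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
               "P", "Q", "R", "S", "T", "V", "W", "Y", "-")
  out <- purrr::map_dfr(seq_along(code$code_columns), function(i) {
    col <- code$code_columns[i]
    ch <- substr(aln$seq, col, col)
    purrr::map_dfr(c("T", "NT"), function(cat) {
      sub <- ch[aln$category == cat]
      cnt <- table(factor(sub, levels = symbols))
      tibble::tibble(code_index = i, column = col, category = cat,
                     residue = symbols, count = as.integer(cnt),
                     freq = as.numeric(cnt) / length(sub),
                     n = length(sub))
    })
  })
  out$category <- factor(out$category, levels = c("T", "NT"))
  class(out) <- unique(c("conservation_profile", class(out)))
  out
}

#' Call key residues from a conservation profile
#'
#' A residue at a code position is a key residue when it is conserved above
#' `t_min` in the threonine-specific category AND represented below `nt_max`
#' in the non-threonine category — strict inequalities on both sides
#' (the study's "> 90% and < 5%" rule). At most one residue per position can
#' qualify when `t_min >= 0.5`.
#'
#' @param profile A `conservation_profile`.
#' @param t_min Minimum T-category frequency, in (0, 1].
#' @param nt_max Maximum NT-category frequency, in [0, 1).
#' @return Tibble: `code_index`, `column`, `residue`, `f_t`, `f_nt`,
#'   `is_key`. One row per (position, residue) present in either category;
#'   filter on `is_key` for the calls.
#' @export
call_key_residues <- function(profile, t_min = 0.90, nt_max = 0.05) {
  stopifnot(inherits(profile, "conservation_profile"))
  if (!(t_min > 0 && t_min <= 1)) stop("t_min must be in (0, 1]", call. = FALSE)
  if (!(nt_max >= 0 && nt_max < 1)) stop("nt_max must be in [0, 1)", call. = FALSE)
  wide <- profile |>
    dplyr::select("code_index", "column", "category", "residue", "freq") |>
    tidyr::pivot_wider(names_from = "category", values_from = "freq",
                       values_fill = 0) |>
    dplyr::rename(f_t = "T", f_nt = "NT")
  wide <- wide[wide$f_t > 0 | wide$f_nt > 0, , drop = FALSE]
  wide$is_key <- wide$f_t > t_min & wide$f_nt < nt_max
  dplyr::arrange(wide, .data$code_index, dplyr::desc(.data$f_t))
}

#' Human-readable conservation report
#'
#' Per-position residue frequency table in percent (1 decimal) for both
#' categories, with key residues flagged.
#'
#' @param profile A `conservation_profile`.
#' @param calls Output of [call_key_residues()] (or `NULL` for no flags).
#' @return Tibble: `code_index`, `column`, `residue`, `pct_T`, `pct_NT`,
#'   `key` (logical flag column, all `FALSE` when `calls` is empty).
#' @export
profile_report <- function(profile, calls = NULL) {
  wide <- profile |>
    dplyr::select("code_index", "column", "category", "residue", "freq") |>
    tidyr::pivot_wider(names_from = "category", values_from = "freq",
                       values_fill = 0)
  out <- tibble::tibble(
    code_index = wide$code_index, column = wide$column, residue = wide$residue,
    pct_T = round(100 * wide$`T`, 1), pct_NT = round(100 * wide$NT, 1)
  )
  out <- out[out$pct_T > 0 | out$pct_NT > 0, , drop = FALSE]
  out$key <- FALSE
  if (!is.null(calls) && nrow(calls) > 0) {
    k <- calls[calls$is_key, c("code_index", "residue"), drop = FALSE]
    out$key <- paste(out$code_index, out$residue) %in%
      paste(k$code_index, k$residue)
  }
  dplyr::arrange(out, .data$code_index, dplyr::desc(.data$pct_T))
}

#' Write key-residue calls as JSON
#'
#' @param calls Output of [call_key_residues()].
#' @param path Output JSON path.
#' @param params Named list of run parameters (thresholds etc.) echoed into
#'   the report.
#' @export
write_key_residue_json <- function(calls, path, params = list()) {
  jsonlite::write_json(list(
    params = params,
    key_residues = as.data.frame(calls[calls$is_key, , drop = FALSE]),
    all_positions = as.data.frame(calls)
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
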