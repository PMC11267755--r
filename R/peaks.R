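#' Construct a peak list
#'
#' A peak list is a tibble of centroided `(mz, intensity)` pairs sorted by
#' m/z, carrying the instrument mode (which sets the default matching
#' tolerance: MALDI 0.3 Da, ESI 0.02 Da) and a label as attributes.
#'
#' @param mz Numeric m/z values (> 0).
#' @param intensity Non-negative intensities (arbitrary units).
#' @param mode `"MALDI"` or `"ESI"`.
#' @param label Free-text label.
#' @return A tibble of class `peaklist` with columns `mz`, `intensity` and
#'   attributes `mode`, `label`.
#' @examples
#' peaklist(c(1334.79, 1031.66), c(100, 30))
#' @export
peaklist <- function(mz, intensity, mode = c("MALDI", "ESI"), label = "") {
  mode <- match.arg(mode)
  stopifnot(is.numeric(mz), is.numeric(intensity), length(mz) == length(intensity))
  if (any(mz <= 0)) stop("peak m/z must be positive", call. = FALSE)
  if (any(intensity < 0)) stop("peak intensity must be >= 0", call. = FALSE)
  ord <- order(mz)
  out <- tibble::tibble(mz = mz[ord], intensity = intensity[ord])
  attr(out, "mode") <- mode
  attr(out, "label") <- label
  class(out) <- unique(c("peaklist", class(out)))
  out
}

#' @export
print.peaklist <- function(x, ...) {
  cat("<peaklist> ", nrow(x), " peaks, mode ", attr(x, "mode"),
      if (nzchar(attr(x, "label") %||% "")) paste0(", '", attr(x, "label"), "'"),
      "\n", sep = "")
  NextMethod()
}

peaklist_mode <- function(x) attr(x, "mode") %||% "MALDI"

#' Read / write peak lists as CSV
#'
#' CSV with columns `mz`, `intensity`.
#'
#' @param path File path.
#' @param mode Instrument mode of the acquired spectrum.
#' @param label Label (defaults to the file name).
#' @return `read_peaklist_csv()` returns a `peaklist`.
#' @export
read_peaklist_csv <- function(path, mode = c("MALDI", "ESI"), label = basename(path)) {
  if (!file.exists(path)) stop("peak list file not found: ", path, call. = FALSE)
  d <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  if (!all(c("mz", "intensity") %in% names(d))) {
    stop("peak list CSV needs columns mz, intensity", call. = FALSE)
  }
  peaklist(d$mz, d$intensity, mode = match.arg(mode), label = label)
}

#' @rdname read_peaklist_csv
#' @param x A `peaklist`.
#' @export
write_peaklist_csv <- function(x, path) {
  readr::write_csv(tibble::tibble(mz = x$mz, intensity = x$intensity), path)
  invisible(path)
}

#' Read / write peak lists as MGF
#'
#' Mascot generic format, one or more `BEGIN IONS`/`END IONS` blocks of
#' whitespace-separated `mz intensity` lines. `PEPMASS` and `CHARGE` headers
#' are honored for ESI precursors and exposed as attributes `pepmass` /
#' `charge`; `TITLE` becomes the label. `read_mgf()` returns the first block
#' unless `all = TRUE`, in which case a list of peak lists is returned.
#'
#' @param path File path.
#' @param mode Instrument mode.
#' @param all Return all blocks as a list.
#' @return A `peaklist`, or a list of them when `all = TRUE`.
#' @export
read_mgf <- function(path, mode = c("MALDI", "ESI"), all = FALSE) {
  if (!file.exists(path)) stop("MGF file not found: ", path, call. = FALSE)
  mode <- match.arg(mode)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  if (length(starts) == 0 || length(starts) != length(ends)) {
    stop("malformed MGF (unbalanced BEGIN IONS/END IONS): ", path, call. = FALSE)
  }
  blocks <- purrr::map2(starts, ends, function(s, e) {
    body <- lines[(s + 1):(e - 1)]
    hdr <- grepl("^[A-Z]+=", body)
    headers <- body[hdr]
    pk <- body[!hdr & nzchar(trimws(body))]
    parts <- strsplit(trimws(pk), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) < 2)
    if (length(bad) > 0) {
      stop("malformed MGF peak line ", s + which(!hdr)[bad[1]], " in ", path,
           call. = FALSE)
    }
    mzv <- as.numeric(vapply(parts, `[`, character(1), 1))
    iv <- as.numeric(vapply(parts, `[`, character(1), 2))
    get_h <- function(key) {
      hit <- grep(paste0("^", key, "="), headers, value = TRUE)
      if (length(hit) == 0) NULL else sub(paste0("^", key, "="), "", hit[1])
    }
    out <- peaklist(mzv, iv, mode = mode, label = get_h("TITLE") %||% basename(path))
    pm <- get_h("PEPMASS")
    if (!is.null(pm)) attr(out, "pepmass") <- as.numeric(strsplit(pm, "\\s+")[[1]][1])
    ch <- get_h("CHARGE")
    if (!is.null(ch)) attr(out, "charge") <- as.integer(gsub("[^0-9]", "", ch))
    out
  })
  if (all) blocks else blocks[[1]]
}

#' @rdname read_mgf
#' @param x A `peaklist`.
#' @param pepmass Optional precursor m/z written as `PEPMASS`.
#' @param charge Optional precursor charge written as `CHARGE`.
#' @export
write_mgf <- function(x, path, pepmass = attr(x, "pepmass"),
                      charge = attr(x, "charge")) {
  lines <- c(
    "BEGIN IONS",
    paste0("TITLE=", attr(x, "label") %||% ""),
    if (!is.null(pepmass)) paste0("PEPMASS=", format(pepmass, digits = 10)),
    if (!is.null(charge)) paste0("CHARGE=", charge, "+"),
    sprintf("%.5f %.6g", x$mz, x$intensity),
    "END IONS"
  )
  writeLines(lines, path)
  invisible(path)
}
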