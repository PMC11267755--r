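test_that("peaks are matched to the nearest candidates within tolerance", {
  cand <- precursor_table(
    enumerate_variants(pvd_scaffold(), 8, c("Thr", "Ser")),
    charges = 1, rda = FALSE)
  obs <- peaklist(c(1320.78, 1334.79), c(40, 100))  # printed MALDI pair
  mr <- match_peaks(obs, cand, tol = 0.3)
  expect_equal(nrow(mr$assignments), 2)
  expect_equal(mr$assignments$label[mr$assignments$peak_mz == 1320.78], "8Ser")
  expect_equal(mr$assignments$label[mr$assignments$peak_mz == 1334.79], "native")
  expect_true(all(abs(mr$assignments$error) <= 0.3))

  empty <- match_peaks(peaklist(numeric(), numeric()), cand, tol = 0.3)
  expect_equal(nrow(empty$assignments), 0)
  no_cand <- match_peaks(obs, cand[0, ], tol = 0.3)
  expect_equal(nrow(no_cand$assignments), 0)
  expect_equal(nrow(no_cand$unmatched_peaks), 2)
})

test_that("equidistant peaks break ties to the lower-mz candidate, flagged", {
  cand <- tibble::tibble(label = c("lo", "hi"), mz = c(99.95, 100.05))
  mr <- match_peaks(peaklist(100, 1), cand, tol = 0.3)
  expect_equal(mr$assignments$label, "lo")
  expect_true(mr$assignments$ambiguous)
})

test_that("greedy matching equals exhaustive minimum-error assignment on
          instrument-realistic instances (oracle)", {
  # candidates >= 1 Da apart, jitter <= tol/3: the regime the spectra occupy.
  # Oracle: full enumeration of injective peak->candidate assignments,
  # maximizing matched count then minimizing total |error|.
  exhaustive_best <- function(obs_mz, cand_mz, tol) {
    n_c <- length(cand_mz)
    recurse <- function(p, used) {
      if (p > length(obs_mz)) return(c(size = 0, cost = 0))
      best <- recurse(p + 1, used)  # leave peak p unmatched
      for (ci in setdiff(seq_len(n_c), used)) {
        e <- abs(obs_mz[p] - cand_mz[ci])
        if (e <= tol) {
          sub <- recurse(p + 1, c(used, ci))
          cand <- c(size = sub[["size"]] + 1, cost = sub[["cost"]] + e)
          if (cand[["size"]] > best[["size"]] ||
              (cand[["size"]] == best[["size"]] &&
                 cand[["cost"]] < best[["cost"]])) best <- cand
        }
      }
      best
    }
    res <- recurse(1, integer())
    list(size = res[["size"]], cost = res[["cost"]])
  }
  withr::with_seed(17, {
    for (rep in 1:25) {
      n_c <- sample(2:6, 1)
      cand_mz <- sort(1000 + cumsum(runif(n_c, 1, 3)))
      n_p <- sample(1:6, 1)
      src <- sample(n_c, n_p, replace = TRUE)
      obs_mz <- sort(cand_mz[src] + rnorm(n_p, 0, 0.1))
      mr <- match_peaks(peaklist(obs_mz, rep(1, n_p)),
                        tibble::tibble(mz = cand_mz), tol = 0.3)
      ex <- exhaustive_best(obs_mz, cand_mz, 0.3)
      expect_equal(nrow(mr$assignments), ex$size)
      expect_equal(sum(abs(mr$assignments$error)), ex$cost, tolerance = 1e-9)
    }
  })
})

test_that("mass shifts map to the study's substitutions", {
  expect_equal(infer_substitution(-14.01, "Thr", tol = 0.15)$candidate, "Ser")
  expect_equal(infer_substitution(12.04, "Thr", tol = 0.15)$candidate, "Leu/Ile")
  expect_equal(infer_substitution(0, "Thr", tol = 0.15)$candidate, "Thr")
  expect_equal(infer_substitution(25.01, "Thr", tol = 0.15)$candidate, "azHA")
  call <- infer_substitution(-14.01, "Thr", tol = 0.15)
  expect_equal(call$nominal_shift, -14L)
})

test_that("an unexplainable shift yields an empty call with nearest misses", {
  expect_message(
    call <- infer_substitution(50.5, "Thr", tol = 0.15),
    "nearest")
  expect_equal(nrow(call), 0)
  expect_equal(nrow(attr(call, "nearest")), 3)
})

test_that("substitution inference inverts the registry (property)", {
  reg <- default_registry()
  alphabet <- reg$id[reg$role == "residue"]
  for (b in alphabet) {
    shift <- unname(block_mass(b) - block_mass("Thr"))
    hit <- infer_substitution(shift, "Thr", alphabet = alphabet, tol = 0.01)
    expect_setequal(hit$candidate, isobars(b))
  }
})

test_that("the -14 y4/y7 pattern localizes to the in-ring threonines", {
  ft <- fragment_table(native_variant())
  shifts <- tibble::tibble(series = c("y", "y", "b", "b", "b", "b"),
                           n = c(4L, 7L, 1L, 2L, 3L, 4L),
                           shift = c(-14.02, -14.02, 0, 0.003, -0.002, 0))
  loc <- localize_from_msms(ft, shifts, native_variant())
  expect_equal(loc$window, c(7L, 8L))
  expect_setequal(unique(loc$candidates$candidate), "Ser")
  expect_equal(loc$nominal_shift, -14L)
  expect_false(loc$ambiguous)
})

test_that("no shifted fragments gives the identity call over the full peptide", {
  ft <- fragment_table(native_variant())
  shifts <- tibble::tibble(series = "y", n = 4L, shift = 0.001)
  loc <- localize_from_msms(ft, shifts, native_variant())
  expect_true(loc$identity)
  expect_equal(loc$window, 1:8)
})

test_that("span set-arithmetic narrows the window (y7-only pattern)", {
  ft <- fragment_table(native_variant())
  shifts <- tibble::tibble(series = c("y", "y"), n = c(7L, 4L),
                           shift = c(-14.02, 0))
  loc <- localize_from_msms(ft, shifts, native_variant())
  # span(y7) minus span(y4) = {2,3,4}; none of Arg/Ser/fOHOrn can lose 14.016
  expect_equal(loc$window_spatial, c(2L, 3L, 4L))
  expect_equal(loc$window, integer(0))
})

test_that("a shifted fragment nested in an unshifted one flags ambiguity", {
  ft <- fragment_table(native_variant())
  shifts <- tibble::tibble(series = c("y", "y"), n = c(4L, 7L),
                           shift = c(-14.02, 0))  # y4 inside unshifted y7
  loc <- localize_from_msms(ft, shifts, native_variant())
  expect_true(loc$ambiguous)
  expect_false(is.null(loc$windows))
})

test_that("spectrum annotation recovers simulated variants end to end", {
  sc <- pvd_scaffold()
  sim <- gen_peaklist(
    tibble::tibble(label = c("native", "8Ser"),
                   variant = list(native_variant(), ser_variant()),
                   abundance = c(100, 30)),
    K = 2, rda_fraction = 0.3, mz_sd = 0.02, intensity_cv = 0.05, seed = 5)
  rep <- annotate_spectrum(sim, sc, c(7, 8), study_alphabet, tol = 0.3)
  conf <- rep[rep$status == "confirmed", ]
  # 7Ser/8Ser are isobaric: recovery is exact at the mass-group level
  ev <- enumerate_variants(sc, c(7, 8), study_alphabet)
  truth_groups <- ev$mass_group[ev$label %in% c("native", "8Ser")]
  expect_setequal(conf$mass_group, truth_groups)
  expect_true(all(rep$n_rda_matched[rep$status == "confirmed"] >= 1))
})

test_that("an RDA companion alone never confirms a species", {
  sc <- pvd_scaffold()
  mh <- ion_mz(neutral_mass(native_variant()))
  obs <- peaklist(rda_companion(mh), 50)
  rep <- annotate_spectrum(obs, sc, c(7, 8), study_alphabet, tol = 0.3)
  expect_equal(rep$status, "companion_only")
  expect_equal(rep$label, "native")

  empty <- annotate_spectrum(peaklist(numeric(), numeric()), sc, c(7, 8),
                             study_alphabet, tol = 0.3)
  expect_equal(nrow(empty), 0)
})

test_that("annotation reports write as JSON and TSV", {
  sc <- pvd_scaffold()
  sim <- gen_peaklist(
    tibble::tibble(label = "native", variant = list(native_variant()),
                   abundance = 100),
    K = 1, rda_fraction = 0.3, seed = 2)
  rep <- annotate_spectrum(sim, sc, c(7, 8), study_alphabet, tol = 0.3)
  jpath <- withr::local_tempfile(fileext = ".json")
  write_annotation_report(rep, jpath, params = list(tol = 0.3))
  parsed <- jsonlite::read_json(jpath)
  expect_equal(parsed$params$tol, 0.3)
  expect_equal(length(parsed$variants), nrow(rep))
  tpath <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_report(rep, tpath)
  expect_equal(nrow(readr::read_tsv(tpath, show_col_types = FALSE)), nrow(rep))
})
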