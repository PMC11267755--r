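mini_alignment <- function(seqs, cats, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("s%02d", seq_along(seqs))
  labeled_alignment(tibble::tibble(id = ids, seq = seqs),
                    tibble::tibble(id = ids, category = cats))
}

test_that("labeled alignments validate length, labels and ids", {
  aln <- mini_alignment(c("ACDEFGHIK", "ACDEFGHIK", "AMDEFGHIK"),
                        c("T", "T", "NT"))
  expect_equal(nrow(aln), 3)
  expect_equal(attr(aln, "alignment_length"), 9)

  expect_error(
    mini_alignment(c("ACDEFGHIK", "ACDEFGHIK", "ACDE"), c("T", "T", "NT"),
                   c("ok1", "ok2", "short1")),
    "short1")
  expect_error(
    labeled_alignment(tibble::tibble(id = c("a", "a"), seq = c("AC", "AC")),
                      tibble::tibble(id = "a", category = "T")),
    "duplicate")
  expect_error(
    labeled_alignment(tibble::tibble(id = c("a", "b"), seq = c("AC", "AC")),
                      tibble::tibble(id = "a", category = "T")),
    "unlabeled.*b")
})

test_that("code position sets demand nine distinct in-range columns", {
  cp <- code_positions(1:8, 9)
  expect_equal(cp$anchor_column, 9L)
  expect_error(code_positions(1:7, 9), "8 code columns")
  expect_error(code_positions(1:8, 8), "distinct")
  expect_error(code_positions(0:7, 9), "1-based")
  aln <- mini_alignment(c("ACDEF"), "T")
  expect_error(frequency_profile(aln, code_positions(1:8, 9)), "exceed")
})

test_that("the Asp anchor filter retains exactly Asp-bearing sequences", {
  cp <- code_positions(1:8, 9)
  all_asp <- mini_alignment(rep("ACDEFGHID", 4), c("T", "T", "NT", "NT"))
  expect_equal(nrow(anchor_filter(all_asp, cp)), 4)

  seqs <- c(rep("ACDEFGHID", 7), rep("ACDEFGHIE", 3))
  mixed <- mini_alignment(seqs, rep(c("T", "NT"), 5))
  filt <- anchor_filter(mixed, cp)
  expect_equal(nrow(filt), 7)
  expect_true(all(substr(filt$seq, 9, 9) == "D"))
  # idempotence
  expect_equal(nrow(anchor_filter(filt, cp)), 7)
  # emptying a category warns, not errors
  t_only_asp <- mini_alignment(c("ACDEFGHID", "ACDEFGHIE"), c("T", "NT"))
  expect_warning(anchor_filter(t_only_asp, cp), "NT")
})

test_that("frequencies are plain counts over category size, gaps included", {
  cp <- code_positions(1:8, 9)
  aln <- mini_alignment(c("AACDEFGHD", "AACDEFGHD", "AACDEFGHD", "GACDEFGHD",
                          "TACDEFGHD"),
                        c(rep("T", 4), "NT"))
  prof <- frequency_profile(aln, cp)
  p1t <- prof[prof$code_index == 1 & prof$category == "T", ]
  expect_equal(p1t$freq[p1t$residue == "A"], 0.75)
  expect_equal(p1t$freq[p1t$residue == "G"], 0.25)
  # single-sequence category: frequencies in {0,1}
  p1nt <- prof[prof$code_index == 1 & prof$category == "NT", ]
  expect_true(all(p1nt$freq %in% c(0, 1)))
  # normalization at every position/category
  sums <- prof |>
    dplyr::group_by(code_index, category) |>
    dplyr::summarise(s = sum(freq), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))

  # gaps dilute conservation: 1 gap among 4 T caps the A frequency at 0.75
  gappy <- mini_alignment(c("AACDEFGHD", "AACDEFGHD", "AACDEFGHD", "-ACDEFGHD",
                            "AACDEFGHD"),
                          c(rep("T", 4), "NT"))
  gprof <- frequency_profile(gappy, cp)
  expect_equal(gprof$freq[gprof$code_index == 1 & gprof$category == "T" &
                            gprof$residue == "A"], 0.75)
  expect_error(frequency_profile(aln[aln$category == "T", ], cp), "nonempty")
})

test_that("key residues require strict > t_min and < nt_max", {
  plant <- function(f_t, f_nt, n_t = 100, n_nt = 100) {
    gen_sequence_set(n_t, n_nt,
                     planted = tibble::tibble(position = 3, residue = "W",
                                              f_t = f_t, f_nt = f_nt),
                     seed = 101)
  }
  cp <- code_positions(1:8, 9)
  # deterministic boundary cases built directly
  boundary <- mini_alignment(
    c(rep("AAWAAAAAD", 9), "AAYAAAAAD", rep("AAGAAAAAD", 10)),
    rep(c("T", "NT"), c(10, 10)))
  calls <- call_key_residues(frequency_profile(boundary, cp))
  w <- calls[calls$code_index == 3 & calls$residue == "W", ]
  expect_equal(w$f_t, 0.9)
  expect_false(w$is_key)  # exactly 0.90 fails the strict inequality

  clear <- mini_alignment(
    c(rep("AAWAAAAAD", 19), "AAYAAAAAD", rep("AAGAAAAAD", 50)),
    rep(c("T", "NT"), c(20, 50)))
  calls2 <- call_key_residues(frequency_profile(clear, cp))
  w2 <- calls2[calls2$code_index == 3 & calls2$residue == "W", ]
  expect_true(w2$is_key)   # f_t = 0.95, f_nt = 0

  expect_error(call_key_residues(frequency_profile(clear, cp), t_min = 1.2),
               "t_min")
  expect_error(call_key_residues(frequency_profile(clear, cp), nt_max = 1),
               "nt_max")
})

test_that("threshold calls equal a brute-force scan (oracle)", {
  aln <- gen_sequence_set(
    60, 150,
    planted = tibble::tibble(position = c(2, 5), residue = c("H", "F"),
                             f_t = c(0.95, 0.7), f_nt = c(0.02, 0.3)),
    seed = 77)
  cp <- attr(aln, "code")
  prof <- frequency_profile(aln, cp)
  calls <- call_key_residues(prof)

  # oracle: independent double loop over positions x symbols on raw counts
  oracle_keys <- list()
  for (p in 1:8) {
    for (sym in unique(prof$residue)) {
      ft <- sum(aln$category == "T" &
                  substr(aln$seq, p, p) == sym) / sum(aln$category == "T")
      fnt <- sum(aln$category == "NT" &
                   substr(aln$seq, p, p) == sym) / sum(aln$category == "NT")
      if (ft > 0.90 && fnt < 0.05) {
        oracle_keys[[length(oracle_keys) + 1]] <- paste(p, sym)
      }
    }
  }
  got <- paste(calls$code_index[calls$is_key], calls$residue[calls$is_key])
  expect_setequal(got, unlist(oracle_keys))
})

test_that("the percent report flags keys and round-trips frequencies", {
  aln <- gen_sequence_set(
    50, 100,
    planted = tibble::tibble(position = 4, residue = "C",
                             f_t = 0.98, f_nt = 0.01),
    seed = 13)
  cp <- attr(aln, "code")
  prof <- frequency_profile(aln, cp)
  calls <- call_key_residues(prof)
  rpt <- profile_report(prof, calls)
  expect_equal(sum(rpt$key), sum(calls$is_key))
  # no calls -> no flags
  rpt0 <- profile_report(prof, NULL)
  expect_false(any(rpt0$key))
  # formatting tolerance: percent at 1 decimal within 0.05% of true freq
  joined <- dplyr::inner_join(
    rpt, prof[prof$category == "T", c("code_index", "residue", "freq")],
    by = c("code_index", "residue"))
  expect_true(all(abs(joined$pct_T / 100 - joined$freq) <= 5e-4))
})

test_that("key-residue calls export to JSON with the thresholds echoed", {
  aln <- gen_sequence_set(
    50, 100,
    planted = tibble::tibble(position = 4, residue = "C",
                             f_t = 0.98, f_nt = 0.01),
    seed = 13)
  calls <- call_key_residues(frequency_profile(aln, attr(aln, "code")))
  path <- withr::local_tempfile(fileext = ".json")
  write_key_residue_json(calls, path,
                         params = list(t_min = 0.9, nt_max = 0.05))
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$params$t_min, 0.9)
  expect_gte(length(parsed$key_residues), 1)
})
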