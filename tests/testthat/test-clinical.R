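dialect_file <- function(lines) {
  f <- tempfile(fileext = ".csv")
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  writeBin(iconv(txt, from = "UTF-8", to = "WINDOWS-1252", toRaw = TRUE)[[1]], f)
  f
}

test_that("the RIS dialect is parsed: $ delimiter, £ quotes, Windows-1252", {
  f <- dialect_file(c("£A£$£B£", "£x$y£$£plain£"))
  out <- read_ris_csv(f, col_names = FALSE)
  expect_equal(unname(unlist(out[1, ])), c("A", "B"))
  expect_equal(out[[1]][2], "x$y")  # delimiter inside quotes is literal
  expect_equal(out[[2]][2], "plain")

  # Windows-1252 byte 0xE9 decodes to e-acute
  f2 <- tempfile()
  q1252 <- iconv("£", from = "UTF-8", to = "WINDOWS-1252", toRaw = TRUE)[[1]]
  writeBin(c(q1252, charToRaw("caf"), as.raw(0xE9), q1252, charToRaw("$"),
             q1252, charToRaw("ok"), q1252, as.raw(0x0A)), f2)
  out2 <- read_ris_csv(f2, col_names = FALSE)
  expect_equal(out2[[1]][1], "café")

  # undecodable byte (0x81 has no Windows-1252 mapping) is reported, not fatal
  f3 <- tempfile()
  writeBin(c(charToRaw("£a£$£b£"), as.raw(0x0A), as.raw(0x81), as.raw(0x0A),
             charToRaw("£c£$£d£"), as.raw(0x0A)), f3)
  out3 <- read_ris_csv(f3, col_names = FALSE)
  expect_equal(nrow(out3), 2L)
  expect_equal(nrow(attr(out3, "bad_rows")), 1L)
})

test_that("the dialect reader agrees with a generic CSV engine on random tables", {
  withr::with_seed(31, {
    cells <- matrix(
      replicate(24, paste(sample(c(letters, "$", "é", " ", ";"), 6, replace = TRUE),
                          collapse = "")),
      nrow = 6
    )
  })
  lines <- apply(cells, 1, function(r) {
    paste(sprintf("£%s£", gsub("£", "££", r)), collapse = "$")
  })
  f <- dialect_file(lines)
  ours <- read_ris_csv(f, col_names = FALSE)
  # oracle: Python's csv module configured with the same dialect
  py <- run_python(sprintf(paste(
    "import csv",
    "with open(r'%s', encoding='cp1252', newline='') as fh:",
    "    for row in csv.reader(fh, delimiter='$', quotechar='£'):",
    "        print('\\x1f'.join(row))",
    sep = "\n"), f))
  oracle <- do.call(rbind, strsplit(py, "\x1f", fixed = TRUE))
  expect_equal(unname(as.matrix(ours)), unname(oracle))
  expect_equal(unname(as.matrix(ours)), unname(cells))
})

test_that("final decisions collapse onto statuses; DISCUSSION as final is an error", {
  expect_equal(collapse_assessment("SELECTION"), "SELECTION")  # e.g. D/D -> Selection
  expect_equal(collapse_assessment("HEALTHY"), "HEALTHY")      # e.g. H/NA -> Healthy
  expect_equal(collapse_assessment("TECHNICAL_RECALL"), "TECHNICAL_RECALL")
  expect_equal(collapse_assessment("NA_DECISION"), "NA_DECISION")
  expect_error(collapse_assessment("DISCUSSION"), class = "mammodb_decision_error")
  expect_error(collapse_assessment("MAYBE"), class = "mammodb_decision_error")
  expect_error(parse_decision("Unsure"), class = "mammodb_decision_error")

  # the collapse reproduces the observed "count as" for every combination
  mix <- default_decision_mix()
  expect_equal(collapse_assessment(mix$final_decision), mix$final_decision)
})

test_that("status summaries tally counts and half-up percentages", {
  expect_equal(summarize_statuses(tibble::tibble(status = character()))$count,
               rep(0L, 4))
  one <- summarize_statuses(tibble::tibble(status = "HEALTHY"))
  expect_equal(one$percent[one$status == "HEALTHY"], 100)

  # brute-force tally oracle on a random status vector
  withr::with_seed(5, {
    sts <- sample(c("HEALTHY", "SELECTION", "TECHNICAL_RECALL", "NA_DECISION"),
                  500, replace = TRUE, prob = c(0.8, 0.1, 0.02, 0.08))
  })
  got <- summarize_statuses(tibble::tibble(status = sts))
  for (s in got$status) {
    expect_equal(got$count[got$status == s], sum(sts == s))
    expect_equal(got$percent[got$status == s],
                 floor(100 * sum(sts == s) / length(sts) * 100 + 0.5) / 100)
  }
})

test_that("registry rows are enum-validated, era-checked, and pseudonymized", {
  f <- tempfile(fileext = ".csv")
  ok_pnr <- sprintf("19591111-111%d", luhn_oracle_check_digit("591111111"))
  writeLines(c(
    "pnr,a_diag_dat,a_pat_sida,a_stud_id,a_tum_storlek",
    sprintf("%s,2017-03-01,1,ST1,14", ok_pnr),
    sprintf("%s,2017-03-01,2,ST2,", ok_pnr),
    sprintf("%s,2017-03-01,3,ST3,10", ok_pnr),      # laterality outside enumeration
    sprintf("%s,2031-03-01,1,ST4,10", ok_pnr),      # outside the registry era
    "19591111-1119,not-a-date,1,ST5,10"
  ), f)
  out <- read_nkbc_csv(f, "salt")
  expect_equal(nrow(out$records) + nrow(out$quarantined), 5L)  # conservation
  expect_equal(nrow(out$records), 2L)
  expect_setequal(out$records$laterality, c("right", "left"))
  expect_match(out$records$person_digest[1], "^[0-9a-f]{64}$")
  expect_match(out$quarantined$reason[1], "enumeration")
  expect_match(out$quarantined$reason[2], "era")
  # retained original row must not carry the raw personal number
  expect_false(any(vapply(out$records$original_row,
                          function(r) any(grepl("19591111", unlist(r))), logical(1))))
})

test_that("reference-standard labelling respects the window and its boundaries", {
  lab <- label_reference_standard(as.Date("2017-01-10"), as.Date("2017-06-01"), 36L)
  expect_true(lab$is_case)
  lab <- label_reference_standard(as.Date("2017-01-10"), as.Date("2020-02-01"), 36L)
  expect_false(lab$is_case)
  # earliest in-window diagnosis is matched
  lab <- label_reference_standard(as.Date("2017-01-10"),
                                  as.Date(c("2019-01-01", "2017-03-01")), 36L)
  expect_equal(lab$matched_diagnosis, as.Date("2017-03-01"))
  # day 0: diagnosis on the screening day counts
  expect_true(label_reference_standard(as.Date("2017-01-10"),
                                       as.Date("2017-01-10"), 36L)$is_case)
  # day -1 does not
  expect_false(label_reference_standard(as.Date("2017-01-10"),
                                        as.Date("2017-01-09"), 36L)$is_case)
  # exact month boundary: +36 months lands on the same day-of-month
  expect_true(label_reference_standard(as.Date("2017-01-10"),
                                       as.Date("2020-01-10"), 36L)$is_case)
  expect_false(label_reference_standard(as.Date("2017-01-10"),
                                        as.Date("2020-01-11"), 36L)$is_case)
  # end-of-month clamping: Jan 31 + 36 months clamps to Jan 31 2020 (leap year ok)
  expect_true(label_reference_standard(as.Date("2016-11-30"),
                                       as.Date("2019-11-30"), 36L)$is_case)
  expect_true(label_reference_standard(as.Date("2017-01-31"),
                                       as.Date("2020-01-31"), 36L)$is_case)

  # monotonicity: enlarging the window never turns a case into a non-case
  withr::with_seed(41, {
    for (i in 1:50) {
      sd <- as.Date("2015-01-01") + sample(0:2000, 1)
      dx <- sd + sample(-100:1500, 3)
      w1 <- sample(1:24, 1); w2 <- w1 + sample(1:24, 1)
      l1 <- label_reference_standard(sd, dx, w1)
      l2 <- label_reference_standard(sd, dx, w2)
      expect_true(!l1$is_case || l2$is_case)
    }
  })
})

test_that("RIS rows become assessment records with hashed person numbers", {
  world <- generate_world(fixture_config(n_patients = 5L, seed = 21L))
  f <- tempfile(fileext = ".csv")
  n <- emit_ris_csv(world, f)
  parsed <- parse_ris_rows(read_ris_csv(f), "salty")
  expect_equal(nrow(parsed$records), n)
  expect_equal(nrow(parsed$quarantined), 0L)
  expect_equal(anyDuplicated(parsed$records$request_number), 0L)
  expect_true(all(grepl("^[0-9a-f]{64}$", parsed$records$person_digest)))
  expect_true(all(parsed$records$pnr_score == 15L))  # generated numbers are valid
  expect_equal(parsed$records$status,
               collapse_assessment(parsed$records$final_decision))
  # dashed and plain formats of the same person collapse to one digest
  by_person <- split(parsed$records$person_digest, world$decisions$person_number)
  expect_true(all(vapply(by_person, function(d) length(unique(d)) == 1L, logical(1))))
})
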