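test_that("identifier hashing is real SHA-512/256 and salt-sensitive", {
  # published test vectors of the function (empty salt == plain digest)
  expect_equal(hash_identifier("abc", ""),
               "53048e2681941ef99b2e29b76b4c7dabe4c2d0c634fc6d46e0e2f13107e7af23")
  expect_error(hash_identifier("", ""), "non-empty")  # empty identifiers refused
  expect_equal(hash_identifier("abc", "s"), hash_identifier("abc", "s"))
  expect_false(hash_identifier("abc", "s1") == hash_identifier("abc", "s2"))
  expect_match(hash_identifier("P001", "s"), "^[0-9a-f]{64}$")

  # independent reference implementation on random inputs (salt-first concat)
  withr::with_seed(9, {
    values <- replicate(5, paste(sample(c(letters, 0:9), 12, replace = TRUE),
                                 collapse = ""))
  })
  py <- run_python(sprintf(paste(
    "import hashlib",
    "for v in %s:",
    "    print(hashlib.new('sha512_256', ('salty' + v).encode()).hexdigest())",
    sep = "\n"),
    paste0("[", paste(sprintf("'%s'", values), collapse = ","), "]")))
  expect_equal(hash_identifier(values, "salty"), py)
})

test_that("long inputs cross block boundaries correctly", {
  # exercises the 112..127-byte padding edge and multi-block messages
  for (n in c(111, 112, 127, 128, 300)) {
    v <- paste(rep("a", n), collapse = "")
    py <- run_python(sprintf(
      "import hashlib; print(hashlib.new('sha512_256', b'%s').hexdigest())", v))
    expect_equal(hash_identifier(v, ""), py, info = sprintf("len %d", n))
  }
})

test_that("characteristics are binned: DOB day dropped, 5-unit rounding half-up", {
  tags <- list(
    PatientBirthDate = te("19560723", "DA"),
    PatientWeight = te(72, "DS"),
    PatientSize = te(1.63, "DS"),
    PatientAge = te("063Y", "AS")
  )
  out <- bin_characteristics(tags)
  expect_equal(out$PatientBirthDate$value, "195607")
  expect_equal(out$PatientWeight$value, 70)
  expect_equal(out$PatientSize$value, 1.65)
  expect_equal(out$PatientAge$value, "065Y")

  # fixed point on multiples of 5; half rounds up (oracle: floor(x/5+.5)*5)
  expect_equal(bin_characteristics(list(PatientWeight = te(70)))$PatientWeight$value, 70)
  expect_equal(bin_characteristics(list(PatientWeight = te(72.5)))$PatientWeight$value, 75)
  withr::with_seed(12, {
    for (w in runif(20, 40, 120)) {
      expect_equal(bin_characteristics(list(PatientWeight = te(w)))$PatientWeight$value,
                   floor(w / 5 + 0.5) * 5)
    }
  })
  bad <- bin_characteristics(list(PatientWeight = te("heavy")))
  expect_null(bad$PatientWeight)
  expect_equal(attr(bad, "dropped"), "PatientWeight")
})

test_that("profile application hashes, preserves, retains, removes — idempotently", {
  profile <- deid_profile("topsecret")
  tags <- list(
    PatientID = te("19391231-9387"),
    AccessionNumber = te("ACC123", "SH"),
    StudyID = te("ST9", "SH"),
    AcquisitionTime = te("101530", "TM"),
    StudyDescription = te("Screening mammography"),
    StationName = te("MAMMO01", "SH"),
    InstitutionName = te("Hospital X"),
    StudyDate = te("20190304", "DA"),
    PatientName = te("Doe^Jane", "PN"),
    PatientWeight = te(68, "DS")
  )
  out <- apply_profile(tags, profile)
  expect_match(out$PatientID$value, "^[0-9a-f]{64}$")
  expect_false(identical(out$PatientID$value, "19391231-9387"))
  expect_match(out$AccessionNumber$value, "^[0-9a-f]{64}$")
  expect_equal(out$AcquisitionTime$value, "101530")        # preserved
  expect_equal(out$StudyDescription$value, "Screening mammography")
  expect_equal(out$StationName$value, "MAMMO01")           # device identity retained
  expect_equal(out$InstitutionName$value, "Hospital X")    # institution retained
  expect_equal(out$StudyDate$value, "20190304")            # full dates retained
  expect_null(out$PatientName)                             # base action: removed
  expect_equal(out$PatientIdentityRemoved$value, "YES")
  # no original value of any hashed tag survives anywhere in the mapping
  flat <- unlist(out, use.names = FALSE)
  expect_false(any(c("19391231-9387", "ACC123", "ST9") %in% flat))
  # applying twice == applying once (no hash-of-hash)
  expect_identical(apply_profile(out, profile), out)
})

test_that("personal-number scoring awards the four bits independently", {
  expect_equal(validate_pnr("")$score, 0L)
  expect_equal(validate_pnr("--..  ")$score, 0L)
  expect_equal(validate_pnr("ABCDEFGHIJKL")$score, 3L)  # alnum + length only
  s <- validate_pnr("ABCDEFGHIJKL")
  expect_equal(unname(s$bits), c(TRUE, TRUE, FALSE, FALSE))

  # full score: check digit computed by the independent Luhn oracle
  stem <- "121212121"
  d <- luhn_oracle_check_digit(stem)
  full <- sprintf("19121212-121%d", d)
  expect_equal(validate_pnr(full)$score, 15L)
  # toggling only the last digit flips at most the checksum bit
  wrong <- sprintf("19121212-121%d", (d + 1) %% 10)
  expect_equal(validate_pnr(wrong)$score, 7L)
  expect_equal(validate_pnr(full)$bits[1:3], validate_pnr(wrong)$bits[1:3])
})

test_that("scoring matches the independent Luhn oracle on random strings", {
  withr::with_seed(77, {
    pool <- c(0:9, LETTERS[1:4], "-", "+")
    for (i in 1:800) {
      n <- sample(c(8:13), 1)
      raw <- paste(sample(pool, n, replace = TRUE), collapse = "")
      got <- validate_pnr(raw)
      clean <- gsub("[^0-9A-Za-z]", "", raw)
      digits <- if (nchar(clean) == 12) substr(clean, 3, 12)
                else if (nchar(clean) == 10) clean else ""
      expected_chk <- grepl("^[0-9]{10}$", digits) && luhn_oracle_valid(digits)
      expect_equal(unname(got$bits[["checksum"]]), expected_chk, info = raw)
      expect_equal(got$score,
                   sum(c(1L, 2L, 4L, 8L) *
                         c(nzchar(clean), nchar(clean) == 12, got$bits[["date"]],
                           expected_chk)))
    }
  })
})

test_that("format-equivalent personal numbers hash identically", {
  salt <- "s"
  a <- normalize_and_hash_pnr("190001015678", salt)
  b <- normalize_and_hash_pnr("19000101-5678", salt)
  expect_equal(a$digest, b$digest)

  # 10-digit form: century inferred so implied age is in [0, 100) — "000101"
  # at a 2021 reference date implies a birth in 2000, not 1900
  ten <- normalize_and_hash_pnr("0001015678", salt, reference_date = as.Date("2021-12-31"))
  expect_equal(ten$digest, normalize_and_hash_pnr("20000101-5678", salt)$digest)
  old <- normalize_and_hash_pnr("4001011234", salt, reference_date = as.Date("2021-12-31"))
  expect_equal(old$digest, normalize_and_hash_pnr("194001011234", salt)$digest)

  expect_false(normalize_and_hash_pnr("194001011234", salt)$digest ==
                 normalize_and_hash_pnr("194001011235", salt)$digest)
  # uncanonicalizable input is hashed as cleaned and flagged by a low score
  junk <- normalize_and_hash_pnr("not-a-number", salt)
  expect_false(junk$score$bits[["date"]])
  expect_equal(junk$digest, hash_identifier("notanumber", salt))
})
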