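#' Salted SHA-512/256 digest of an identifier
#'
#' Hashes `salt || value` with SHA-512/256 and returns the lowercase hex
#' digest (64 characters).  The concatenation order (salt first) and the hex
#' encoding are fixed constants of this package.  With an empty salt the
#' digest equals the published SHA-512/256 value of the input itself, which
#' is how the primitive is verified.  Deterministic; vectorized over `value`.
#'
#' @param value Character vector of non-empty identifiers.
#' @param salt Secret salt string (may be empty only for verification).
#' @return Character vector of 64-hex-character digests.
#' @export
hash_identifier <- function(value, salt) {
  stopifnot(is.character(salt), length(salt) == 1L)
  value <- as.character(value)
  if (length(value) == 0L) return(character())
  if (any(is.na(value) | !nzchar(value))) {
    abort("identifiers must be non-empty; normalize before hashing")
  }
  salt_raw <- charToRaw(enc2utf8(salt))
  vapply(value, function(v) {
    dg <- .Call(C_sha512_256, c(salt_raw, charToRaw(enc2utf8(v))))
    paste(sprintf("%02x", as.integer(dg)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Round to the nearest multiple of `unit`, half away from zero.  Base round()
# is banker's rounding, which would bin 72.5 kg down.
round_to_unit <- function(x, unit) {
  floor(x / unit + 0.5) * unit
}

#' Pseudonymization profile
#'
#' Describes how a DICOM tag mapping is pseudonymized: a fixed list of
#' identifiers replaced by salted SHA-512/256 digests; patient
#' characteristics binned to coarser values; a set of preserved attributes;
#' and the retained categories (institution identity, device identity, and
#' longitudinal temporal information with full dates).  Everything else that
#' is identifying falls to the base action: removal.  The salt is held only
#' inside the profile object and is never written to any output document.
#'
#' @param salt Secret salt string used for all identifier hashing.
#' @return An object of class `deid_profile`.
#' @export
deid_profile <- function(salt) {
  stopifnot(is.character(salt), length(salt) == 1L)
  structure(list(
    salt = salt,
    hashed_tags = c("PatientID", "AccessionNumber", "AdmissionID",
                    "InterpretationID", "PerformedProcedureStepID",
                    "PerformingPhysicianName", "RequestedProcedureID",
                    "ResultsID", "StudyID"),
    preserved_tags = c("AcquisitionTime", "StudyDescription"),
    # Retained option categories pass through unchanged.
    retained_tags = c(
      # institution identity
      "InstitutionName", "InstitutionAddress",
      # device identity
      "StationName", "Manufacturer", "ManufacturerModelName",
      "DeviceSerialNumber", "SoftwareVersions",
      # longitudinal temporal information with full dates
      "StudyDate", "StudyTime", "SeriesDate", "SeriesTime",
      "AcquisitionDate", "ContentDate", "PatientAge"
    ),
    # Base-profile action (remove) for the remaining identifying attributes.
    removed_tags = c("PatientName", "OtherPatientIDs", "IssuerOfPatientID",
                     "PatientAddress", "PatientTelephoneNumbers",
                     "ReferringPhysicianName", "OperatorsName")
  ), class = "deid_profile")
}

#' @export
print.deid_profile <- function(x, ...) {
  cat("<deid_profile> hashed:", length(x$hashed_tags),
      "tags; preserved:", length(x$preserved_tags),
      "; retained:", length(x$retained_tags),
      "; removed:", length(x$removed_tags), "(salt withheld)\n")
  invisible(x)
}

#' Bin patient characteristics to coarser intervals
#'
#' Reduces re-identification risk on the characteristics that are kept:
#' the day is removed from the date of birth (year and month remain);
#' weight (kg) is rounded to intervals of 5 kg; body height is rounded to
#' intervals of 5 cm (DICOM `PatientSize` is in metres, so the bin is
#' 0.05 m); age is rounded to intervals of 5 years.  Rounding is to the
#' nearest bin with halves rounding up.  Absent fields stay absent; a
#' non-numeric quantity is dropped and reported as an attribute of the
#' result.
#'
#' @param tags A DICOM tag mapping (keyword -> `list(vr, value)`).
#' @return The mapping with binned characteristics; dropped fields are
#'   listed in `attr(, "dropped")`.
#' @export
bin_characteristics <- function(tags) {
  dropped <- character()
  dob <- tags[["PatientBirthDate"]]
  if (!is.null(dob)) {
    v <- as.character(dob$value)[1]
    if (grepl("^[0-9]{8}$", v)) {
      tags[["PatientBirthDate"]]$value <- substr(v, 1, 6)
    } else if (grepl("^[0-9]{6}$", v)) {
      # already year+month
    } else {
      tags[["PatientBirthDate"]] <- NULL
      dropped <- c(dropped, "PatientBirthDate")
    }
  }
  bin_numeric <- function(keyword, unit) {
    entry <- tags[[keyword]]
    if (is.null(entry)) return()
    num <- suppressWarnings(as.numeric(entry$value[1]))
    if (is.na(num)) {
      tags[[keyword]] <<- NULL
      dropped <<- c(dropped, keyword)
    } else {
      tags[[keyword]]$value <<- round_to_unit(num, unit)
    }
  }
  bin_numeric("PatientWeight", 5)     # kg
  bin_numeric("PatientSize", 0.05)    # metres, i.e. 5 cm
  age <- tags[["PatientAge"]]
  if (!is.null(age)) {
    v <- as.character(age$value)[1]
    m <- regmatches(v, regexec("^([0-9]{1,3})([DWMY]?)$", v))[[1]]
    if (length(m) == 3L) {
      unit <- if (nzchar(m[3])) m[3] else "Y"
      yrs <- round_to_unit(as.numeric(m[2]), if (unit == "Y") 5 else 1)
      tags[["PatientAge"]]$value <- sprintf("%03d%s", as.integer(yrs), unit)
    } else {
      tags[["PatientAge"]] <- NULL
      dropped <- c(dropped, "PatientAge")
    }
  }
  attr(tags, "dropped") <- dropped
  tags
}

#' Pseudonymize a DICOM tag mapping
#'
#' Applies the profile to a tag mapping: the listed identifiers are replaced
#' by salted SHA-512/256 digests, patient characteristics are binned
#' ([bin_characteristics()]), preserved and retained attributes pass through
#' unchanged, and the remaining identifying attributes are removed.  The
#' output carries no original value of any hashed tag.  The mapping is
#' marked with `PatientIdentityRemoved = "YES"` and a
#' `DeidentificationMethod` note; applying the profile to an
#' already-marked mapping is a no-op, so digests are never re-hashed.
#'
#' @param tags A DICOM tag mapping (keyword -> `list(vr, value)`).
#' @param profile A [deid_profile()].
#' @return The pseudonymized tag mapping.
#' @export
apply_profile <- function(tags, profile) {
  stopifnot(inherits(profile, "deid_profile"))
  marked <- tags[["PatientIdentityRemoved"]]
  if (!is.null(marked) && identical(as.character(marked$value), "YES")) {
    return(tags)
  }
  for (kw in profile$hashed_tags) {
    entry <- tags[[kw]]
    if (is.null(entry)) next
    v <- paste(as.character(entry$value), collapse = "\\")
    if (!nzchar(v)) {
      tags[[kw]] <- NULL
    } else {
      tags[[kw]] <- list(vr = "LO", value = hash_identifier(v, profile$salt))
    }
  }
  tags <- bin_characteristics(tags)
  for (kw in profile$removed_tags) tags[[kw]] <- NULL
  tags[["PatientIdentityRemoved"]] <- list(vr = "CS", value = "YES")
  tags[["DeidentificationMethod"]] <- list(
    vr = "LO",
    value = "modified basic profile: salted SHA-512/256 identifiers, binned characteristics"
  )
  tags
}

#' Pseudonymize every indexed image of a project
#'
#' Rewrites the `dicom_tags` of each `ImageMetadata` document through
#' [apply_profile()] and promotes the hashed `PatientID` digest to
#' `patient_digest` at the body root.  Safe to re-run: already-marked
#' documents are untouched.
#'
#' @inheritParams ds_insert
#' @param profile A [deid_profile()].
#' @return Number of documents rewritten.
#' @export
deidentify_project <- function(store, project, profile) {
  n <- 0L
  for (id in ds_ids(store, "ImageMetadata", project)) {
    doc <- ds_get(store, "ImageMetadata", id)
    tags <- doc$body$dicom_tags
    marked <- tags[["PatientIdentityRemoved"]]
    if (!is.null(marked) && identical(as.character(marked$value), "YES")) next
    new_tags <- apply_profile(tags, profile)
    patch <- list(dicom_tags = new_tags)
    pid <- new_tags[["PatientID"]]
    if (!is.null(pid)) patch$patient_digest <- pid$value
    ds_update(store, "ImageMetadata", id, patch)
    n <- n + 1L
  }
  n
}

# Luhn mod-10 check over a digit string where doubling starts on the first
# digit (the rule used for Swedish personal numbers on YYMMDDXXX + check).
luhn_check <- function(digits10) {
  d <- as.integer(strsplit(digits10, "")[[1]])
  if (length(d) != 10L || anyNA(d)) return(FALSE)
  w <- rep(c(2L, 1L), 5L)
  p <- d * w
  s <- sum(p %/% 10L + p %% 10L)
  s %% 10L == 0L
}

luhn_check_digit <- function(digits9) {
  d <- as.integer(strsplit(digits9, "")[[1]])
  stopifnot(length(d) == 9L, !anyNA(d))
  w <- rep(c(2L, 1L), length.out = 9L)
  p <- d * w
  s <- sum(p %/% 10L + p %% 10L)
  (10L - s %% 10L) %% 10L
}

pnr_clean <- function(raw) {
  gsub("[^0-9A-Za-z]", "", as.character(raw))
}

pnr_date_part <- function(clean) {
  if (nchar(clean) == 12L) substr(clean, 3L, 8L)
  else if (nchar(clean) == 10L) substr(clean, 1L, 6L)
  else NA_character_
}

pnr_valid_date <- function(yymmdd) {
  if (is.na(yymmdd) || !grepl("^[0-9]{6}$", yymmdd)) return(FALSE)
  # century-agnostic validity: the month/day must form a real calendar date
  !is.na(strptime(paste0("20", yymmdd), "%Y%m%d", tz = "UTC")) ||
    !is.na(strptime(paste0("19", yymmdd), "%Y%m%d", tz = "UTC"))
}

#' Validate a Swedish personal number before hashing
#'
#' Cleans the raw string (all non-alphanumeric characters deleted) and
#' awards four independent bits, summed into a score from 0 to 15 that is
#' stored alongside the digest to assert comparability of two hashed
#' personal numbers:
#' * 1 — all characters alphanumeric (after cleaning this holds whenever
#'   anything remains; see the note below);
#' * 2 — correct length (12 characters, `YYYYMMDDXXXX`);
#' * 4 — a valid date parses from the `YYMMDD` part;
#' * 8 — the last digit is the correct Luhn mod-10 checksum of the nine
#'   digits `YYMMDDXXX`.
#'
#' The alphanumeric bit is evaluated on the cleaned string, where it is
#' satisfied by any non-empty input; it is kept for fidelity to the scoring
#' scheme rather than discriminative power.  Never raises: degenerate
#' inputs simply score low.
#'
#' @param raw Personal number in any of its common formats
#'   (`19000101-5678`, `190001015678`, `0001015678`, ...).
#' @return A `pnr_score`: list with `score` (0–15) and named logical `bits`
#'   (`alnum`, `length`, `date`, `checksum`).
#' @export
validate_pnr <- function(raw) {
  clean <- pnr_clean(raw)
  bits <- c(
    alnum = nzchar(clean),
    length = nchar(clean) == 12L,
    date = pnr_valid_date(pnr_date_part(clean)),
    checksum = FALSE
  )
  digits <- if (nchar(clean) == 12L) substr(clean, 3L, 12L)
            else if (nchar(clean) == 10L) clean
            else NA_character_
  if (!is.na(digits) && grepl("^[0-9]{10}$", digits)) {
    bits[["checksum"]] <- luhn_check(digits)
  }
  structure(list(
    score = sum(bits * c(1L, 2L, 4L, 8L)),
    bits = bits
  ), class = "pnr_score")
}

#' @export
print.pnr_score <- function(x, ...) {
  cat("<pnr_score>", x$score, "(",
      paste(names(x$bits)[x$bits], collapse = "+"), ")\n")
  invisible(x)
}

# Century inference for 10-digit personal numbers: pick the century that
# puts the implied age in [0, 100) at the reference date.
pnr_canonicalize <- function(clean, reference_date) {
  if (nchar(clean) == 12L && grepl("^[0-9]{12}$", clean) &&
      pnr_valid_date(substr(clean, 3L, 8L))) {
    return(clean)
  }
  if (nchar(clean) == 10L && grepl("^[0-9]{10}$", clean) &&
      pnr_valid_date(substr(clean, 1L, 6L))) {
    for (century in c("20", "19", "18")) {
      birth <- strptime(paste0(century, substr(clean, 1L, 6L)), "%Y%m%d", tz = "UTC")
      if (is.na(birth)) next
      birth <- as.Date(birth)
      age <- as.numeric(reference_date - birth) / 365.25
      if (age >= 0 && age < 100) return(paste0(century, clean))
    }
  }
  NULL
}

#' Normalize and hash a personal number
#'
#' The same individual's personal number arrives in several formats
#' (`19000101-5678`, `190001015678`, `0001015678`), which would hash to
#' different digests.  This cleans the input, canonicalizes it to the
#' 12-character `YYYYMMDDXXXX` form when recoverable (10-digit forms get
#' their century inferred so the implied age lies in \[0, 100) at
#' `reference_date`), and hashes the canonical form with
#' [hash_identifier()].  Uncanonicalizable input is hashed as-cleaned and is
#' flagged by its low validation score (date bit unset).
#'
#' @inheritParams validate_pnr
#' @param salt Secret salt string.
#' @param reference_date Date used for century inference (default: the
#'   latest date such inference is stable for screening-era data).
#' @return List with `digest` (64-hex digest) and `score` (a `pnr_score`).
#' @export
normalize_and_hash_pnr <- function(raw, salt, reference_date = as.Date("2021-12-31")) {
  clean <- pnr_clean(raw)
  score <- validate_pnr(raw)
  canonical <- pnr_canonicalize(clean, reference_date)
  target <- canonical %||% clean
  if (!nzchar(target)) {
    abort("personal number is empty after cleaning", class = "mammodb_pnr_error")
  }
  list(digest = hash_identifier(target, salt), score = score)
}
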