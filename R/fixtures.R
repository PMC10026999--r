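#' Default double-reading decision mix
#'
#' The 28 combinations of (first, second, final) decisions observed in
#' Swedish screening double reading, with their unique-request-number
#' counts.  Used as the default `decision_mix` of the synthetic world
#' generator (weights proportional to the counts, so synthetic marginals
#' resemble a real screening program) and as the canonical worked input for
#' the decision-collapse summary.
#'
#' @return Tibble with columns `first_decision`, `second_decision`,
#'   `final_decision` (decision levels) and `n` (count).
#' @export
default_decision_mix <- function() {
  rows <- c(
    "HEALTHY,HEALTHY,HEALTHY,812089",
    "HEALTHY,NA_DECISION,HEALTHY,263044",
    "NA_DECISION,NA_DECISION,NA_DECISION,149740",
    "DISCUSSION,DISCUSSION,SELECTION,17986",
    "DISCUSSION,HEALTHY,HEALTHY,14604",
    "HEALTHY,DISCUSSION,HEALTHY,9796",
    "NA_DECISION,NA_DECISION,SELECTION,8967",
    "HEALTHY,DISCUSSION,SELECTION,5616",
    "DISCUSSION,DISCUSSION,HEALTHY,5593",
    "DISCUSSION,HEALTHY,SELECTION,3329",
    "DISCUSSION,NA_DECISION,SELECTION,3229",
    "DISCUSSION,NA_DECISION,HEALTHY,954",
    "HEALTHY,NA_DECISION,TECHNICAL_RECALL,333",
    "DISCUSSION,DISCUSSION,TECHNICAL_RECALL,318",
    "DISCUSSION,HEALTHY,TECHNICAL_RECALL,241",
    "HEALTHY,HEALTHY,TECHNICAL_RECALL,221",
    "HEALTHY,DISCUSSION,TECHNICAL_RECALL,180",
    "HEALTHY,NA_DECISION,SELECTION,132",
    "NA_DECISION,NA_DECISION,TECHNICAL_RECALL,74",
    "NA_DECISION,DISCUSSION,SELECTION,45",
    "NA_DECISION,NA_DECISION,HEALTHY,9",
    "DISCUSSION,NA_DECISION,TECHNICAL_RECALL,8",
    "NA_DECISION,HEALTHY,SELECTION,5",
    "SELECTION,NA_DECISION,SELECTION,5",
    "HEALTHY,HEALTHY,SELECTION,3",
    "SELECTION,SELECTION,SELECTION,3",
    "TECHNICAL_RECALL,HEALTHY,HEALTHY,1",
    "DISCUSSION,TECHNICAL_RECALL,TECHNICAL_RECALL,1"
  )
  parts <- do.call(rbind, strsplit(rows, ",", fixed = TRUE))
  tibble(
    first_decision = parts[, 1],
    second_decision = parts[, 2],
    final_decision = parts[, 3],
    n = as.integer(parts[, 4])
  )
}

#' Expand a decision-combination table into per-examination records
#'
#' Inverse of tabulation: each combination row becomes `n` assessment
#' records with sequential request numbers, with the status collapsed from
#' the final decision.
#'
#' @param mix Tibble as returned by [default_decision_mix()].
#' @return Tibble with one row per examination (`request_number`,
#'   `first_decision`, `second_decision`, `final_decision`, `status`).
#' @export
expand_decision_mix <- function(mix) {
  idx <- rep(seq_len(nrow(mix)), mix$n)
  tibble(
    request_number = sprintf("RQ%08d", seq_along(idx)),
    first_decision = mix$first_decision[idx],
    second_decision = mix$second_decision[idx],
    final_decision = mix$final_decision[idx],
    status = collapse_assessment(mix$final_decision[idx])
  )
}

#' Synthetic-world configuration
#'
#' Controls the generator that emulates the four input sources.  Defaults
#' emulate a screening program at desk scale: the decision mix follows the
#' observed double-reading combination frequencies; the cancer rate matches
#' the ~4% share of ever-diagnosed participants in regional source
#' populations; slot duplication/missingness rates are set to exercise all
#' input-selection cases.
#'
#' @param n_patients Number of synthetic women.
#' @param exams_per_patient Integer range (min, max) of screening exams per
#'   woman.
#' @param duplicate_slot_rate Probability that an occupied view slot holds
#'   two instances.
#' @param missing_slot_rate Probability that a view slot is absent from an
#'   exam.
#' @param cancer_rate Probability that a woman appears in the outcome
#'   registry.
#' @param decision_mix Combination table with weights (see
#'   [default_decision_mix()]).
#' @param seed Integer seed recorded in the world manifest.
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(n_patients = 20L, exams_per_patient = c(1L, 4L),
                           duplicate_slot_rate = 0.1, missing_slot_rate = 0.1,
                           cancer_rate = 0.04,
                           decision_mix = default_decision_mix(), seed = 1L) {
  stopifnot(n_patients >= 1L,
            duplicate_slot_rate >= 0, duplicate_slot_rate <= 1,
            missing_slot_rate >= 0, missing_slot_rate <= 1,
            cancer_rate >= 0, cancer_rate <= 1,
            all(decision_mix$n >= 0))
  structure(list(
    n_patients = as.integer(n_patients),
    exams_per_patient = as.integer(exams_per_patient),
    duplicate_slot_rate = duplicate_slot_rate,
    missing_slot_rate = missing_slot_rate,
    cancer_rate = cancer_rate,
    decision_mix = decision_mix,
    seed = as.integer(seed)
  ), class = "fixture_config")
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_fixture_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_pnr12 <- function(birth_date) {
  yymmdd <- format(birth_date, "%y%m%d")
  xxx <- sprintf("%03d", sample(0:999, 1L))
  chk <- luhn_check_digit(paste0(yymmdd, xxx))
  paste0(format(birth_date, "%Y%m%d"), xxx, chk)
}

#' Generate a synthetic screening world
#'
#' Draws a deterministic (seeded) in-memory world of women, screening
#' exams, DICOM image descriptions, double-reading decisions, and registry
#' diagnoses, with controllable slot duplication/missingness so every
#' input-selection case occurs.  Diagnosis dates are placed at varying
#' offsets after an exam so both reference-standard outcomes (within and
#' beyond the follow-up window) occur in reasonably sized worlds.
#'
#' @param config A [fixture_config()].
#' @return A `fixture_world`: list of tibbles `patients`, `exams`,
#'   `images`, `decisions`, `diagnoses`, plus the `config` (the manifest,
#'   including the seed).
#' @export
generate_world <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  with_fixture_seed(config$seed, {
    n <- config$n_patients
    birth <- as.Date("1940-01-01") + sample(0:(365 * 36), n, replace = TRUE)
    pnr <- vapply(seq_len(n), function(i) random_pnr12(birth[i]), character(1))
    while (anyDuplicated(pnr)) {  # personal numbers must identify uniquely
      dup <- which(duplicated(pnr))
      pnr[dup] <- vapply(dup, function(i) random_pnr12(birth[i]), character(1))
    }
    patients <- tibble(
      patient_index = seq_len(n),
      person_number = pnr,
      patient_id = pnr,  # hospitals key images by the personal number
      birth_date = birth
    )

    exams <- list(); images <- list(); decisions <- list()
    exam_no <- 0L; image_no <- 0L
    for (i in seq_len(n)) {
      lo <- config$exams_per_patient[1]; hi <- config$exams_per_patient[2]
      k <- if (lo == hi) lo else sample(lo:hi, 1L)
      dates <- sort(as.Date("2008-01-01") + sample(0:(365 * 14 - 1), k))
      for (d in seq_len(k)) {
        exam_no <- exam_no + 1L
        exam_id <- sprintf("E%05d", exam_no)
        study_uid <- sprintf("%s.2.%d", UID_ROOT, exam_no)
        series_uid <- sprintf("%s.3.%d", UID_ROOT, exam_no)
        exam_date <- dates[d]
        age <- floor(as.numeric(exam_date - birth[i]) / 365.25)
        exams[[exam_no]] <- tibble(
          exam_id = exam_id, patient_index = i,
          person_number = pnr[i],
          exam_date = exam_date,
          study_uid = study_uid,
          age = age
        )
        inst <- 0L
        for (slot in VIEW_SLOTS) {
          if (stats::runif(1) < config$missing_slot_rate) next
          n_inst <- if (stats::runif(1) < config$duplicate_slot_rate) 2L else 1L
          for (r in seq_len(n_inst)) {
            image_no <- image_no + 1L; inst <- inst + 1L
            lat <- sub("-.*", "", slot); view <- sub(".*-", "", slot)
            sop_rank <- sample(0:2, 1L, prob = c(0.9, 0.05, 0.05))
            images[[image_no]] <- tibble(
              image_no = image_no,
              exam_id = exam_id,
              patient_index = i,
              sop_instance_uid = sprintf("%s.4.%d", UID_ROOT, image_no),
              series_uid = series_uid,
              study_uid = study_uid,
              laterality = lat, view = view,
              sop_class_uid = SOP_CLASS_PRIORITY[sop_rank + 1L],
              acquisition_time = sprintf("%02d%02d%02d", 8L + inst %% 10L,
                                         sample(0:59, 1L), sample(0:59, 1L)),
              instance_number = inst,
              subdir = paste(sprintf("d%02d", sample(1:6, sample(1:3, 1L), replace = TRUE)),
                             collapse = "/")
            )
          }
        }
        mix <- config$decision_mix
        ci <- sample(nrow(mix), 1L, prob = mix$n / sum(mix$n))
        decisions[[exam_no]] <- tibble(
          request_number = sprintf("RQ%07d", exam_no),
          exam_id = exam_id,
          person_number = pnr[i],
          screening_date = exam_date,
          first_decision = mix$first_decision[ci],
          second_decision = mix$second_decision[ci],
          final_decision = mix$final_decision[ci]
        )
      }
    }
    exams <- bind_rows(exams); images <- bind_rows(images)
    decisions <- bind_rows(decisions)

    diagnosed <- which(stats::runif(n) < config$cancer_rate)
    diagnoses <- map(diagnosed, function(i) {
      pe <- exams[exams$patient_index == i, ]
      idx <- sample(nrow(pe), 1L)
      offset <- sample(30:1200, 1L)  # spans both sides of a 36-month window
      dx <- min(pe$exam_date[idx] + offset, as.Date("2021-12-31"))
      tibble(person_number = pnr[i], diagnosis_date = dx,
             laterality_code = sample(c("1", "2"), 1L),
             study_ref = pe$study_uid[idx],
             tumor_size_mm = sample(4:40, 1L))
    })
    diagnoses <- if (length(diagnoses)) bind_rows(diagnoses) else {
      tibble(person_number = character(), diagnosis_date = as.Date(character()),
             laterality_code = character(), study_ref = character(),
             tumor_size_mm = integer())
    }
    structure(list(config = config, patients = patients, exams = exams,
                   images = images, decisions = decisions, diagnoses = diagnoses),
              class = "fixture_world")
  })
}

#' @export
print.fixture_world <- function(x, ...) {
  cat("<fixture_world> seed", x$config$seed, ":",
      nrow(x$patients), "patients,", nrow(x$exams), "exams,",
      nrow(x$images), "images,", nrow(x$diagnoses), "diagnoses\n")
  invisible(x)
}

#' Write a synthetic DICOM tree
#'
#' One `.dcm` file per image, in randomized nested folders (to exercise
#' recursive scanning), each with minimal valid headers — identity and
#' hierarchy UIDs, patient demographics, view/laterality, SOP class,
#' acquisition time and instance number — a tiny 8x8 pixel payload (headers
#' are the object of study), and one private element to exercise the
#' private-tag exclusion rule.
#'
#' @param world A `fixture_world`.
#' @param root Output directory (created if needed).
#' @return Number of files written.
#' @export
emit_dicom_tree <- function(world, root) {
  stopifnot(inherits(world, "fixture_world"))
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  pixel <- as.raw(rep(seq_len(64L) %% 256L, each = 2L))  # 8x8, 16-bit
  for (i in seq_len(nrow(world$images))) {
    im <- world$images[i, ]
    ex <- world$exams[world$exams$exam_id == im$exam_id, ]
    pat <- world$patients[world$patients$patient_index == im$patient_index, ]
    dir <- file.path(root, im$subdir)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    dcm_write(
      file.path(dir, paste0(im$sop_instance_uid, ".dcm")),
      tags = list(
        SOPClassUID = im$sop_class_uid,
        SOPInstanceUID = im$sop_instance_uid,
        StudyInstanceUID = im$study_uid,
        SeriesInstanceUID = im$series_uid,
        PatientID = pat$patient_id,
        PatientName = sprintf("Synthetic^Participant%04d", im$patient_index),
        PatientBirthDate = format(pat$birth_date, "%Y%m%d"),
        PatientSex = "F",
        AccessionNumber = sprintf("ACC%05d", match(im$exam_id, world$exams$exam_id)),
        StudyDate = format(ex$exam_date, "%Y%m%d"),
        StudyTime = "090000",
        AcquisitionTime = im$acquisition_time,
        InstanceNumber = im$instance_number,
        Modality = "MG",
        ImageLaterality = im$laterality,
        ViewPosition = im$view,
        StudyDescription = "Screening mammography",
        InstitutionName = "Synthetic Hospital",
        Manufacturer = "SyntheticVendor",
        StationName = sprintf("MAMMO%02d", im$patient_index %% 3L + 1L),
        Rows = 8L, Columns = 8L, BitsAllocated = 16L, BitsStored = 16L,
        HighBit = 15L, PixelRepresentation = 0L, SamplesPerPixel = 1L,
        PhotometricInterpretation = "MONOCHROME2"
      ),
      pixel = pixel,
      private = c(internal_note = "synthetic private element")
    )
  }
  nrow(world$images)
}

# Source-format strings for decisions (inverse of the parse mapping).
decision_to_source <- function(x) {
  inv <- stats::setNames(names(DECISION_STRINGS), DECISION_STRINGS)
  unname(inv[x])
}

#' Write the assessment table in the RIS dialect
#'
#' Emits the world's decision table byte-for-byte in the non-standard
#' dialect that [read_ris_csv()] expects: Windows-1252 encoding, `$` column
#' delimiter, `£` string delimiter.  Personal numbers alternate between
#' dashed and plain formats to exercise canonicalization before hashing.
#'
#' @param world A `fixture_world`.
#' @param path Output file path.
#' @return Number of data rows written.
#' @export
emit_ris_csv <- function(world, path) {
  stopifnot(inherits(world, "fixture_world"))
  d <- world$decisions
  header <- write_dialect_line(c("request_number", "person_number", "screening_date",
                                 "first_decision", "second_decision", "final_decision"))
  lines <- vapply(seq_len(nrow(d)), function(i) {
    pn <- d$person_number[i]
    if (i %% 2L == 0L) pn <- paste0(substr(pn, 1, 8), "-", substr(pn, 9, 12))
    write_dialect_line(c(d$request_number[i], pn, format(d$screening_date[i]),
                         decision_to_source(d$first_decision[i]),
                         decision_to_source(d$second_decision[i]),
                         decision_to_source(d$final_decision[i])))
  }, character(1))
  txt <- paste0(paste(c(header, lines), collapse = "\n"), "\n")
  bytes <- iconv(txt, from = "UTF-8", to = "WINDOWS-1252", toRaw = TRUE)[[1]]
  writeBin(bytes, path)
  nrow(d)
}

#' Write the registry outcome table
#'
#' UTF-8 comma-separated table with the schema-named columns of
#' [nkbc_schema_default()], including the coded `a_pat_sida` laterality
#' column.
#'
#' @param world A `fixture_world`.
#' @param path Output file path.
#' @return Number of data rows written.
#' @export
emit_nkbc_csv <- function(world, path) {
  stopifnot(inherits(world, "fixture_world"))
  d <- world$diagnoses
  out <- data.frame(
    pnr = d$person_number,
    a_diag_dat = format(d$diagnosis_date),
    a_pat_sida = d$laterality_code,
    a_stud_id = d$study_ref,
    a_tum_storlek = d$tumor_size_mm,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  nrow(out)
}

#' Write synthetic vendor inference payloads
#'
#' One payload per exam that has at least one image, in the vendor's
#' dialect: per-image or per-laterality scores (JSON) or a DICOM dataset
#' carrying the findings.  The per-laterality dialect embeds an encoded
#' overlay-image field so the exclusion rule is exercised.  Scores are
#' deterministic under the world's seed.
#'
#' @param world A `fixture_world`.
#' @param profile A [vendor_profile()].
#' @param dir Output directory.
#' @return Number of payload files written.
#' @export
emit_vendor_payloads <- function(world, profile, dir) {
  stopifnot(inherits(world, "fixture_world"), inherits(profile, "vendor_profile"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_out <- 0L
  with_fixture_seed(world$config$seed + 1L, {
    for (eid in unique(world$images$exam_id)) {
      ims <- world$images[world$images$exam_id == eid, ]
      ex <- world$exams[world$exams$exam_id == eid, ]
      n_out <- n_out + 1L
      if (profile$style == "per_image") {
        payload <- list(
          study_uid = ex$study_uid,
          results = map(seq_len(nrow(ims)), function(j) {
            list(image_uid = ims$sop_instance_uid[j],
                 laterality = ims$laterality[j],
                 score = round(stats::runif(1), 4))
          })
        )
      } else {
        payload <- list(
          study_uid = ex$study_uid,
          scores = list(right = round(stats::runif(1), 4),
                        left = round(stats::runif(1), 4)),
          overlay_png = paste(sample(c(LETTERS, letters, 0:9), 64, replace = TRUE),
                              collapse = "")
        )
      }
      if (profile$format == "dicom") {
        dcm_write(
          file.path(dir, paste0(eid, "_result.dcm")),
          tags = list(
            SOPInstanceUID = sprintf("%s.5.%d", UID_ROOT, n_out),
            StudyInstanceUID = ex$study_uid,
            ImageComments = as.character(
              jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
            )
          )
        )
      } else {
        jsonlite::write_json(payload, file.path(dir, paste0(eid, "_result.json")),
                             auto_unbox = TRUE, digits = NA)
      }
    }
  })
  n_out
}

#' Tabular views of a synthetic world for population selection
#'
#' Bridges the generator to the population module: returns the exam,
#' outcome and assessment tables keyed by the salted person digest, exactly
#' as they would look after ingestion and pseudonymization.
#'
#' @param world A `fixture_world`.
#' @param salt Secret salt string.
#' @return List of tibbles `exams` (`person_digest`, `exam_id`,
#'   `exam_date`, `age`), `outcomes` (`person_digest`, `diagnosis_date`,
#'   `laterality`), `assessments` (`person_digest`, `request_number`,
#'   `status`).
#' @export
world_tables <- function(world, salt) {
  stopifnot(inherits(world, "fixture_world"))
  digest_of <- function(pn) hash_identifier(pn, salt)
  exams <- world$exams |>
    mutate(person_digest = digest_of(.data$person_number)) |>
    select("person_digest", "exam_id", "exam_date", "age")
  outcomes <- world$diagnoses
  outcomes <- if (nrow(outcomes)) {
    outcomes |>
      mutate(person_digest = digest_of(.data$person_number),
             laterality = ifelse(.data$laterality_code == "1", "right", "left")) |>
      select("person_digest", "diagnosis_date", "laterality")
  } else {
    tibble(person_digest = character(), diagnosis_date = as.Date(character()),
           laterality = character())
  }
  assessments <- world$decisions |>
    mutate(person_digest = digest_of(.data$person_number),
           status = ifelse(.data$final_decision == "DISCUSSION", NA_character_,
                           .data$final_decision)) |>
    select("person_digest", "request_number", "status")
  list(exams = exams, outcomes = outcomes, assessments = assessments)
}
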