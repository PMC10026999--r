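#' Merge tag mappings by intersection-allow-missing-minority
#'
#' Combines the DICOM tag mappings of the members of a series or study into
#' the mapping of tags they can be said to share.  For each tag keyword seen
#' anywhere, three cases are distinguished:
#' 1. present in every mapping with equal values: kept;
#' 2. present with differing values: disagreement, discarded;
#' 3. missing in some mappings but equal wherever present: kept iff the tag
#'    is present in a *strict* majority of the mappings (a tie — e.g. present
#'    in exactly one of two images — is discarded rather than fabricating a
#'    consensus).
#'
#' The operation is invariant to the order of the input mappings, and any
#' kept value appears verbatim in every mapping that has the key.
#'
#' @param tag_maps Non-empty list of tag mappings (keyword -> entry).
#' @return The shared tag mapping.
#' @examples
#' merge_tags_iamm(list(list(A = 1), list(A = 1), list()))  # kept: 2 of 3
#' merge_tags_iamm(list(list(A = 1), list(A = 2)))          # conflict: dropped
#' @export
merge_tags_iamm <- function(tag_maps) {
  if (!is.list(tag_maps) || length(tag_maps) == 0L) {
    abort("tag_maps must be a non-empty list of tag mappings")
  }
  n <- length(tag_maps)
  keys <- unique(unlist(lapply(tag_maps, names)))
  out <- list()
  for (k in keys) {
    vals <- lapply(tag_maps, function(m) m[[k]])
    present <- !vapply(vals, is.null, logical(1))
    pvals <- vals[present]
    first <- pvals[[1]]
    if (!all(vapply(pvals, identical, logical(1), y = first))) next
    if (sum(present) * 2L > n) out[[k]] <- first
  }
  out
}

#' Combine DICOM date and time strings into an ISO 8601 datetime
#'
#' Promotes the raw `StudyDate` (DA, `YYYYMMDD`) and optional `StudyTime`
#' (TM, `HHMMSS[.ffffff]`) strings kept at ingestion time into a sortable
#' ISO 8601 string, enabling calendar arithmetic when defining populations.
#' A missing time defaults to midnight; fractional seconds are truncated.
#'
#' @param study_date 8-digit DICOM DA string.
#' @param study_time Optional DICOM TM string.
#' @return ISO 8601 datetime string, e.g. `"2017-01-15T09:30:00"`.
#' @export
parse_study_datetime <- function(study_date, study_time = NULL) {
  study_date <- as.character(study_date)
  if (length(study_date) != 1L || !grepl("^[0-9]{8}$", study_date)) {
    abort(sprintf("invalid DICOM date '%s'", study_date),
          class = "mammodb_promotion_error")
  }
  if (is.null(study_time) || length(study_time) == 0L || is.na(study_time) ||
      !nzchar(as.character(study_time))) {
    study_time <- "000000"
  }
  study_time <- sub("\\..*$", "", as.character(study_time))  # drop fractional seconds
  if (!grepl("^[0-9]{6}$", study_time)) {
    abort(sprintf("invalid DICOM time '%s'", study_time),
          class = "mammodb_promotion_error")
  }
  dt <- strptime(paste0(study_date, study_time), "%Y%m%d%H%M%S", tz = "UTC")
  if (is.na(dt)) {
    abort(sprintf("invalid calendar datetime '%s %s'", study_date, study_time),
          class = "mammodb_promotion_error")
  }
  format(dt, "%Y-%m-%dT%H:%M:%S")
}

tag_value <- function(tags, keyword) {
  v <- tags[[keyword]]$value
  if (is.null(v)) NULL else as.character(v)
}

image_tag_maps <- function(store, ids) {
  lapply(ids, function(id) ds_get(store, "ImageMetadata", id)$body$dicom_tags)
}

#' Build RadiologicalSeries documents from indexed images
#'
#' Groups `ImageMetadata` documents by `SeriesInstanceUID`; each group
#' becomes one `RadiologicalSeries` document carrying the member image ids
#' and the shared tags under [merge_tags_iamm()], and each member image is
#' back-linked with the database-assigned `series_id`.  Re-running is
#' idempotent: groups whose series already exists are skipped.  Images
#' lacking a `SeriesInstanceUID` are reported, never silently grouped.
#'
#' @inheritParams ds_insert
#' @return A `build_report`: `n_created`, `n_skipped`, `missing_key_ids`,
#'   `errors`.
#' @export
build_series <- function(store, project) {
  ds_register(store, c("ImageMetadata", "RadiologicalSeries"))
  existing <- unique(map_chr(ds_docs(store, "RadiologicalSeries", project),
                             function(d) d$body$series_uid))
  groups <- ds_group_by(store, "ImageMetadata", "dicom_tags.SeriesInstanceUID.value",
                        project)
  n_created <- 0L; n_skipped <- 0L; missing_ids <- character()
  for (i in seq_len(nrow(groups))) {
    uid <- groups[[1]][i]
    ids <- groups$ids[[i]]
    if (uid == MISSING_KEY) {
      missing_ids <- c(missing_ids, ids)
      next
    }
    if (uid %in% existing) {
      n_skipped <- n_skipped + 1L
      next
    }
    shared <- merge_tags_iamm(image_tag_maps(store, ids))
    sid <- ds_insert(store, "RadiologicalSeries", list(
      series_uid = uid,
      image_ids = as.list(ids),
      image_count = length(ids),
      dicom_tags = shared
    ), project)
    for (id in ids) ds_update(store, "ImageMetadata", id, list(series_id = sid))
    n_created <- n_created + 1L
  }
  structure(list(n_created = n_created, n_skipped = n_skipped,
                 missing_key_ids = missing_ids, errors = tibble(id = character(),
                                                                reason = character())),
            class = "build_report")
}

#' Build RadiologicalStudy documents from indexed images
#'
#' Groups images directly by the unique combination of `PatientID` and
#' `StudyDate` (the DICOM notion of a study being one patient on one
#' calendar day).  Each group becomes a `RadiologicalStudy` with:
#' * `patient_pseudo_id` — the grouping `PatientID` value (a salted digest
#'   once the project has been pseudonymized);
#' * `date` — `StudyDate`/`StudyTime` promoted to ISO 8601 via
#'   [parse_study_datetime()];
#' * `modality` and `study_uid` — the exact unions of the values seen across
#'   member images (a study keeps every `StudyInstanceUID` it spans);
#' * `dicom_tags` — the shared mapping under [merge_tags_iamm()];
#' * `image_ids` / `image_count`.
#'
#' Member images are back-linked with `study_id`.  Images lacking either
#' grouping key are reported; date-promotion failures are recorded on the
#' report and leave the study without a `date` field.
#'
#' @inheritParams ds_insert
#' @return A `build_report` (see [build_series()]).
#' @export
build_studies <- function(store, project) {
  ds_register(store, c("ImageMetadata", "RadiologicalStudy"))
  existing <- unique(map_chr(ds_docs(store, "RadiologicalStudy", project),
                             function(d) paste(d$body$patient_pseudo_id,
                                               d$body$study_date_raw, sep = "\x1f")))
  groups <- ds_group_by(
    store, "ImageMetadata",
    c("dicom_tags.PatientID.value", "dicom_tags.StudyDate.value"), project
  )
  n_created <- 0L; n_skipped <- 0L; missing_ids <- character()
  err_id <- character(); err_reason <- character()
  for (i in seq_len(nrow(groups))) {
    pid <- groups[[1]][i]; sdate <- groups[[2]][i]
    ids <- groups$ids[[i]]
    if (pid == MISSING_KEY || sdate == MISSING_KEY) {
      missing_ids <- c(missing_ids, ids)
      next
    }
    if (paste(pid, sdate, sep = "\x1f") %in% existing) {
      n_skipped <- n_skipped + 1L
      next
    }
    maps <- image_tag_maps(store, ids)
    shared <- merge_tags_iamm(maps)
    modality <- sort(unique(unlist(lapply(maps, tag_value, "Modality"))))
    study_uid <- sort(unique(unlist(lapply(maps, tag_value, "StudyInstanceUID"))))
    iso <- tryCatch(
      parse_study_datetime(sdate, tag_value(shared, "StudyTime")),
      mammodb_promotion_error = function(e) {
        err_id <<- c(err_id, ids[1]); err_reason <<- c(err_reason, conditionMessage(e))
        NULL
      }
    )
    body <- list(
      patient_pseudo_id = pid,
      date = iso,
      study_date_raw = sdate,
      modality = as.list(modality),
      study_uid = as.list(study_uid),
      image_ids = as.list(ids),
      image_count = length(ids),
      dicom_tags = shared
    )
    stid <- ds_insert(store, "RadiologicalStudy", body, project)
    for (id in ids) ds_update(store, "ImageMetadata", id, list(study_id = stid))
    n_created <- n_created + 1L
  }
  structure(list(n_created = n_created, n_skipped = n_skipped,
                 missing_key_ids = missing_ids,
                 errors = tibble(id = err_id, reason = err_reason)),
            class = "build_report")
}

#' Build Patient documents from studies
#'
#' Groups `RadiologicalStudy` documents by `patient_pseudo_id`; each group
#' becomes one `Patient` document listing its study ids, and every member
#' study is back-linked with the database-assigned `patient_id`.
#' Idempotent on re-run.
#'
#' @inheritParams ds_insert
#' @return A `build_report` (see [build_series()]).
#' @export
build_patients <- function(store, project) {
  ds_register(store, c("RadiologicalStudy", "Patient"))
  existing <- unique(map_chr(ds_docs(store, "Patient", project),
                             function(d) d$body$patient_pseudo_id))
  groups <- ds_group_by(store, "RadiologicalStudy", "patient_pseudo_id", project)
  n_created <- 0L; n_skipped <- 0L; missing_ids <- character()
  for (i in seq_len(nrow(groups))) {
    pid <- groups[[1]][i]
    ids <- groups$ids[[i]]
    if (pid == MISSING_KEY) {
      missing_ids <- c(missing_ids, ids)
      next
    }
    if (pid %in% existing) {
      n_skipped <- n_skipped + 1L
      next
    }
    paid <- ds_insert(store, "Patient", list(
      patient_pseudo_id = pid,
      study_ids = as.list(ids)
    ), project)
    for (id in ids) ds_update(store, "RadiologicalStudy", id, list(patient_id = paid))
    n_created <- n_created + 1L
  }
  structure(list(n_created = n_created, n_skipped = n_skipped,
                 missing_key_ids = missing_ids,
                 errors = tibble(id = character(), reason = character())),
            class = "build_report")
}

#' Build the full series/study/patient hierarchy
#'
#' Convenience wrapper running [build_series()], [build_studies()] and
#' [build_patients()] in order.
#'
#' @inheritParams ds_insert
#' @return Named list of the three `build_report`s.
#' @export
build_hierarchy <- function(store, project) {
  list(
    series = build_series(store, project),
    studies = build_studies(store, project),
    patients = build_patients(store, project)
  )
}

#' @export
print.build_report <- function(x, ...) {
  cat("<build_report> created:", x$n_created, " skipped:", x$n_skipped,
      " missing-key images:", length(x$missing_key_ids), "\n")
  if (nrow(x$errors) > 0) print(x$errors)
  invisible(x)
}
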