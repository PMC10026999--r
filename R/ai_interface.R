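VIEW_SLOTS <- c("R-MLO", "L-MLO", "R-CC", "L-CC")

# SOP Class UIDs accepted for mammography inference input, in priority
# order (rank 0 is preferred).
SOP_CLASS_PRIORITY <- c(
  "1.2.840.10008.5.1.4.1.1.1.2",    # digital mammography x-ray image, for presentation
  "1.2.840.10008.5.1.4.1.1.1.2.1",  # second-priority mammography storage class
  "1.2.840.10008.5.1.4.1.1.1"       # computed radiography image storage
)

tm_to_seconds <- function(x) {
  x <- sub("\\..*$", "", as.character(x))
  ifelse(grepl("^[0-9]{6}$", x),
         as.numeric(substr(x, 1, 2)) * 3600 +
           as.numeric(substr(x, 3, 4)) * 60 +
           as.numeric(substr(x, 5, 6)),
         NA_real_)
}

#' Qualify mammography instances for AI input
#'
#' Asserts the headers needed for input selection on each candidate image:
#' image laterality (`R`/`L`), view position (`MLO`/`CC`), and an accepted
#' SOP class (ranked by the fixed priority order).  Acquisition time and
#' instance number (the fallback ordering key when acquisition time is
#' absent) are carried along for the recency ordering.  Images failing any
#' assertion are rejected with a per-image reason, never fatally.
#'
#' @param images Tibble with columns `image_id`, `laterality`, `view`,
#'   `sop_class_uid`, and optionally `acquisition_time` (DICOM TM string)
#'   and `instance_number`.
#' @return List with `qualified` (tibble: `image_id`, `slot`,
#'   `acquisition_time`, `instance_number`, `sop_class_rank`) and
#'   `rejected` (tibble: `image_id`, `reason`).
#' @export
qualify_images <- function(images) {
  if (!all(c("image_id", "laterality", "view", "sop_class_uid") %in% names(images))) {
    abort("images must have image_id, laterality, view, sop_class_uid columns")
  }
  if (is.null(images$acquisition_time)) images$acquisition_time <- NA_character_
  if (is.null(images$instance_number)) images$instance_number <- NA_integer_
  ok_id <- character(); slot <- character(); acq <- character(); inst <- integer()
  rank <- integer(); rej_id <- character(); rej_reason <- character()
  for (i in seq_len(nrow(images))) {
    lat <- as.character(images$laterality[i])
    view <- as.character(images$view[i])
    sop <- as.character(images$sop_class_uid[i])
    reason <- NULL
    if (is.na(lat) || !lat %in% c("R", "L")) {
      reason <- sprintf("laterality '%s' not R/L", lat)
    } else if (is.na(view) || !view %in% c("MLO", "CC")) {
      reason <- sprintf("view position '%s' not MLO/CC", view)
    } else if (is.na(sop) || !sop %in% SOP_CLASS_PRIORITY) {
      reason <- sprintf("SOP class '%s' not accepted", sop)
    }
    if (!is.null(reason)) {
      rej_id <- c(rej_id, as.character(images$image_id[i]))
      rej_reason <- c(rej_reason, reason)
      next
    }
    ok_id <- c(ok_id, as.character(images$image_id[i]))
    slot <- c(slot, paste0(lat, "-", view))
    acq <- c(acq, as.character(images$acquisition_time[i]))
    inst <- c(inst, suppressWarnings(as.integer(images$instance_number[i])))
    rank <- c(rank, match(sop, SOP_CLASS_PRIORITY) - 1L)
  }
  list(
    qualified = tibble(image_id = ok_id, slot = slot, acquisition_time = acq,
                       instance_number = inst, sop_class_rank = rank),
    rejected = tibble(image_id = rej_id, reason = rej_reason)
  )
}

#' Qualify the instances of a stored study
#'
#' Store-backed wrapper over [qualify_images()]: pulls the member images of
#' a `RadiologicalStudy` document and maps their DICOM tags
#' (`ImageLaterality`, `ViewPosition`, `SOPClassUID`, `AcquisitionTime`,
#' `InstanceNumber`) onto the qualification columns.
#'
#' @inheritParams ds_insert
#' @param study_id Id of a `RadiologicalStudy` document.
#' @return As [qualify_images()].
#' @export
qualify_instances <- function(store, study_id) {
  study <- ds_get(store, "RadiologicalStudy", study_id)
  if (is.null(study)) abort(sprintf("no study '%s'", study_id))
  ids <- unlist(study$body$image_ids)
  rows <- map(ids, function(id) {
    tags <- ds_get(store, "ImageMetadata", id)$body$dicom_tags
    g <- function(kw) {
      v <- tags[[kw]]$value
      if (is.null(v)) NA_character_ else as.character(v)[1]
    }
    tibble(image_id = id, laterality = g("ImageLaterality"), view = g("ViewPosition"),
           sop_class_uid = g("SOPClassUID"), acquisition_time = g("AcquisitionTime"),
           instance_number = suppressWarnings(as.integer(g("InstanceNumber"))))
  })
  qualify_images(bind_rows(rows))
}

# Deterministic total order within a slot: acquisition time, then instance
# number (the fallback), then SOP-class rank, then UID lexicographically.
# Unknown keys order after known ones at each level.
slot_ordering <- function(q) {
  order(tm_to_seconds(q$acquisition_time), q$instance_number, q$sop_class_rank,
        q$image_id, na.last = FALSE)
  # na.last = FALSE puts unknown-keyed instances first, i.e. "oldest"; the
  # newest pick therefore prefers instances with known acquisition times.
}

pick_per_slot <- function(qualified, newest) {
  picks <- character()
  for (s in VIEW_SLOTS) {
    q <- qualified[qualified$slot == s, , drop = FALSE]
    if (nrow(q) == 0L) next
    ord <- slot_ordering(q)
    picks <- c(picks, q$image_id[if (newest) ord[length(ord)] else ord[1]])
  }
  picks
}

#' Classify a study's qualified instances into an input case
#'
#' Input selection targets the four view slots R-MLO, L-MLO, R-CC, L-CC.
#' Exactly one of four outcome families applies to any non-empty qualified
#' set:
#' * **case 1** — every slot occupied by exactly one instance: one
#'   four-instance input set;
#' * **cases 2a/2b** — every slot occupied, at least one multiply: two
#'   four-instance sets, taking per slot the most recent (2a) and the
#'   oldest (2b) instance;
#' * **case 3** — some slots missing, each present slot single: one set
#'   with fewer than four instances;
#' * **cases 4a/4b** — some slots missing, some present slot multiple: two
#'   sets with fewer than four instances (most recent / oldest per slot).
#'
#' Recency is resolved per slot independently by acquisition time, falling
#' back to instance number, then SOP-class rank, then UID, so the choice is
#' always deterministic.
#'
#' @param qualified The `qualified` tibble from [qualify_images()].
#' @return List with `cases` (character vector, e.g. `c("CASE_2A",
#'   "CASE_2B")`) and `input_sets` (list of character vectors of image ids,
#'   ordered R-MLO, L-MLO, R-CC, L-CC); both empty for an empty input.
#' @export
classify_input_case <- function(qualified) {
  if (nrow(qualified) == 0L) {
    return(list(cases = character(), input_sets = list()))
  }
  occ <- vapply(VIEW_SLOTS, function(s) sum(qualified$slot == s), integer(1))
  missing_any <- any(occ == 0L)
  multiple_any <- any(occ >= 2L)
  if (!missing_any && !multiple_any) {
    list(cases = "CASE_1", input_sets = list(pick_per_slot(qualified, newest = TRUE)))
  } else if (!missing_any) {
    list(cases = c("CASE_2A", "CASE_2B"),
         input_sets = list(pick_per_slot(qualified, newest = TRUE),
                           pick_per_slot(qualified, newest = FALSE)))
  } else if (!multiple_any) {
    list(cases = "CASE_3", input_sets = list(pick_per_slot(qualified, newest = TRUE)))
  } else {
    list(cases = c("CASE_4A", "CASE_4B"),
         input_sets = list(pick_per_slot(qualified, newest = TRUE),
                           pick_per_slot(qualified, newest = FALSE)))
  }
}

#' Reduce per-image scores to one score per laterality
#'
#' When more than one score exists for an examination side, the maximum per
#' laterality is used.  Idempotent and invariant to input order; an absent
#' side is omitted from the result (sparse representation).
#'
#' @param scores Data frame with columns `laterality` (`"R"`/`"L"`) and
#'   `score`, or a list of `list(laterality =, score =)` pairs.
#' @return Named list with up to two elements `R` and `L`.
#' @export
reduce_scores <- function(scores) {
  if (is.data.frame(scores)) {
    lat <- as.character(scores$laterality); sc <- as.numeric(scores$score)
  } else {
    lat <- map_chr(scores, function(s) as.character(s$laterality))
    sc <- map_dbl(scores, function(s) as.numeric(s$score))
  }
  stopifnot(all(is.finite(sc)) || length(sc) == 0L)
  out <- list()
  for (side in c("R", "L")) {
    if (any(lat == side)) out[[side]] <- max(sc[lat == side])
  }
  out
}

normalize_laterality <- function(x) {
  m <- c(R = "R", L = "L", RIGHT = "R", LEFT = "L", right = "R", left = "L",
         Right = "R", Left = "L")
  out <- unname(m[as.character(x)])
  if (anyNA(out)) abort(sprintf("unknown laterality label(s): %s",
                                paste(unique(x[is.na(out)]), collapse = ", ")))
  out
}

#' Vendor inference dialect profiles
#'
#' Vendor output dialects are declarative configurations — field paths into
#' the payload — rather than hard-coded parsers, so new vendors register by
#' configuration.  Three profiles ship, mimicking the payload shapes seen
#' in practice: a JSON dialect with one score per image, a JSON dialect
#' with one score per laterality (plus an embedded encoded-image overlay
#' field that must never be persisted), and a DICOM-dataset dialect whose
#' findings travel inside a dataset rather than a JSON file.  Each profile
#' also declares the vendor's input capabilities (which input-set shapes it
#' accepts).
#'
#' @param name Profile name; one of `"imagewise_json"`, `"sidewise_json"`,
#'   `"dataset_dicom"`.
#' @return A `vendor_profile` object.
#' @export
vendor_profile <- function(name) {
  profiles <- list(
    imagewise_json = list(
      name = "imagewise_json", format = "json", style = "per_image",
      fields = list(study = "study_uid", scores = "results",
                    laterality = "laterality", score = "score", image = "image_uid"),
      exclude_fields = character(),
      capabilities = list(single = TRUE, four_view = TRUE, priors = 2L,
                          other_modalities = FALSE)
    ),
    sidewise_json = list(
      name = "sidewise_json", format = "json", style = "per_laterality",
      fields = list(study = "study_uid", right = c("scores", "right"),
                    left = c("scores", "left")),
      exclude_fields = "overlay_png",
      capabilities = list(single = FALSE, four_view = TRUE, priors = 2L,
                          other_modalities = FALSE)
    ),
    dataset_dicom = list(
      name = "dataset_dicom", format = "dicom", style = "per_image",
      fields = list(study = "study_uid", scores = "results",
                    laterality = "laterality", score = "score", image = "image_uid"),
      exclude_fields = character(),
      capabilities = list(single = TRUE, four_view = TRUE, priors = 2L,
                          other_modalities = FALSE)
    )
  )
  p <- profiles[[name]]
  if (is.null(p)) {
    abort(sprintf("unknown vendor profile '%s'", name), class = "mammodb_registry_error")
  }
  structure(p, class = "vendor_profile")
}

payload_path <- function(payload, path) {
  for (p in path) {
    if (!is.list(payload) || is.null(payload[[p]])) {
      abort(sprintf("missing field '%s' in vendor payload", paste(path, collapse = ".")),
            class = "mammodb_parse_error")
    }
    payload <- payload[[p]]
  }
  payload
}

strip_fields <- function(x, fields) {
  if (!is.list(x)) return(x)
  x[names(x) %in% fields] <- NULL
  map(x, strip_fields, fields = fields)
}

#' Parse a vendor inference payload into the normalized result
#'
#' Reads a vendor payload — a JSON mapping (or path to one), or a
#' DICOM-dataset file for the dataset dialect — and normalizes it: per-image
#' scores are reduced to one score per laterality via [reduce_scores()]
#' (per-laterality dialects pass through), and the complete original
#' payload is retained under `original_data` *except* the declared
#' encoded-image fields, which are stripped recursively.
#'
#' @param payload Named list (parsed JSON), or a file path.
#' @param profile A [vendor_profile()].
#' @return An `inference_result`: `vendor`, `study_ref`,
#'   `scores_by_laterality` (named list, sparse), `per_image_scores`
#'   (tibble or `NULL`), `original_data`.
#' @export
parse_vendor_result <- function(payload, profile) {
  stopifnot(inherits(profile, "vendor_profile"))
  if (is.character(payload) && length(payload) == 1L) {
    payload <- if (profile$format == "dicom") {
      tags <- dcm_read_header(payload)
      comments <- tags[["ImageComments"]]
      if (is.null(comments)) {
        abort("dataset payload lacks the findings element (ImageComments)",
              class = "mammodb_parse_error")
      }
      jsonlite::fromJSON(comments$value, simplifyVector = FALSE)
    } else {
      jsonlite::fromJSON(payload, simplifyVector = FALSE)
    }
  }
  stopifnot(is.list(payload))
  f <- profile$fields
  study_ref <- as.character(payload_path(payload, f$study))
  per_image <- NULL
  if (profile$style == "per_image") {
    items <- payload_path(payload, f$scores)
    per_image <- tibble(
      image = map_chr(items, function(it) as.character(it[[f$image]] %||% NA_character_)),
      laterality = normalize_laterality(map_chr(items, function(it) {
        v <- it[[f$laterality]]
        if (is.null(v)) abort(sprintf("missing field '%s' in vendor payload", f$laterality),
                              class = "mammodb_parse_error")
        as.character(v)
      })),
      score = map_dbl(items, function(it) {
        v <- it[[f$score]]
        if (is.null(v)) abort(sprintf("missing field '%s' in vendor payload", f$score),
                              class = "mammodb_parse_error")
        as.numeric(v)
      })
    )
    scores <- reduce_scores(per_image)
  } else {
    scores <- list()
    r <- tryCatch(payload_path(payload, f$right), mammodb_parse_error = function(e) NULL)
    l <- tryCatch(payload_path(payload, f$left), mammodb_parse_error = function(e) NULL)
    if (is.null(r) && is.null(l)) {
      abort(sprintf("missing score fields '%s'/'%s' in vendor payload",
                    paste(f$right, collapse = "."), paste(f$left, collapse = ".")),
            class = "mammodb_parse_error")
    }
    if (!is.null(r)) scores$R <- as.numeric(r)
    if (!is.null(l)) scores$L <- as.numeric(l)
  }
  structure(list(
    vendor = profile$name,
    study_ref = study_ref,
    scores_by_laterality = scores,
    per_image_scores = per_image,
    original_data = strip_fields(payload, profile$exclude_fields)
  ), class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat("<inference_result>", x$vendor, "study", x$study_ref, "\n")
  for (s in names(x$scores_by_laterality)) {
    cat("  ", s, "=", x$scores_by_laterality[[s]], "\n")
  }
  invisible(x)
}

#' Load vendor inference payloads into the store
#'
#' Parses every payload file in `paths` with the vendor's profile and
#' inserts one `InferenceStudyResult` document each.
#'
#' @inheritParams ds_insert
#' @param paths Payload file paths.
#' @param profile A [vendor_profile()].
#' @return Tibble of per-file outcomes (`path`, `ok`, `study_ref`/`reason`).
#' @export
load_inferences <- function(store, paths, project, profile) {
  ds_register(store, "InferenceStudyResult")
  rows <- map(paths, function(p) {
    res <- tryCatch(parse_vendor_result(p, profile), error = function(e) e)
    if (inherits(res, "error")) {
      tibble(path = p, ok = FALSE, study_ref = NA_character_,
             reason = conditionMessage(res))
    } else {
      body <- list(
        vendor = res$vendor,
        study_ref = res$study_ref,
        scores_by_laterality = res$scores_by_laterality,
        original_data = res$original_data
      )
      if (!is.null(res$per_image_scores)) {
        body$per_image_scores <- purrr::transpose(as.list(res$per_image_scores))
      }
      ds_insert(store, "InferenceStudyResult", body, project)
      tibble(path = p, ok = TRUE, study_ref = res$study_ref, reason = NA_character_)
    }
  })
  bind_rows(rows)
}

#' Plan which input sets are submitted to a vendor
#'
#' Applies the vendor capability matrix: vendors accepting four-image exams
#' receive each input set whole; a vendor accepting only single images
#' receives the sets split into singletons.  Sets from modalities a vendor
#' does not accept never reach this point (they are rejected at
#' qualification).
#'
#' @param profile A [vendor_profile()].
#' @param input_sets List of character vectors of image ids (from
#'   [classify_input_case()]).
#' @return List of character vectors: the units to submit.
#' @export
plan_inference_inputs <- function(profile, input_sets) {
  stopifnot(inherits(profile, "vendor_profile"))
  if (isTRUE(profile$capabilities$four_view)) {
    input_sets
  } else if (isTRUE(profile$capabilities$single)) {
    unlist(map(input_sets, function(s) map(s, identity)), recursive = FALSE)
  } else {
    list()
  }
}
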