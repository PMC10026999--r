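# DICOM support covers only what header indexing needs: explicit-VR
# little-endian datasets, string and short binary value representations,
# defined-length sequences (skipped).  Parsing stops at the PixelData
# element, so indexing a file touches only its header region.

# Tag dictionary: the standard attributes this toolkit writes, promotes, or
# acts on during pseudonymization.  Unknown even-group tags are still read
# (keyed "Xggggeeee"); private (odd-group) tags are ignored entirely.
dicom_dictionary <- function() {
  d <- c(
    "0008,0005,CS,SpecificCharacterSet",
    "0008,0016,UI,SOPClassUID",
    "0008,0018,UI,SOPInstanceUID",
    "0008,0020,DA,StudyDate",
    "0008,0021,DA,SeriesDate",
    "0008,0022,DA,AcquisitionDate",
    "0008,0023,DA,ContentDate",
    "0008,0030,TM,StudyTime",
    "0008,0031,TM,SeriesTime",
    "0008,0032,TM,AcquisitionTime",
    "0008,0050,SH,AccessionNumber",
    "0008,0060,CS,Modality",
    "0008,0070,LO,Manufacturer",
    "0008,0080,LO,InstitutionName",
    "0008,0081,ST,InstitutionAddress",
    "0008,0090,PN,ReferringPhysicianName",
    "0008,1010,SH,StationName",
    "0008,1030,LO,StudyDescription",
    "0008,103E,LO,SeriesDescription",
    "0008,1050,PN,PerformingPhysicianName",
    "0008,1070,PN,OperatorsName",
    "0008,1090,LO,ManufacturerModelName",
    "0010,0010,PN,PatientName",
    "0010,0020,LO,PatientID",
    "0010,0021,LO,IssuerOfPatientID",
    "0010,0030,DA,PatientBirthDate",
    "0010,0040,CS,PatientSex",
    "0010,1000,LO,OtherPatientIDs",
    "0010,1010,AS,PatientAge",
    "0010,1020,DS,PatientSize",
    "0010,1030,DS,PatientWeight",
    "0010,1040,LO,PatientAddress",
    "0010,2154,SH,PatientTelephoneNumbers",
    "0012,0062,CS,PatientIdentityRemoved",
    "0012,0063,LO,DeidentificationMethod",
    "0018,1000,LO,DeviceSerialNumber",
    "0018,1020,LO,SoftwareVersions",
    "0018,5101,CS,ViewPosition",
    "0020,000D,UI,StudyInstanceUID",
    "0020,000E,UI,SeriesInstanceUID",
    "0020,0010,SH,StudyID",
    "0020,0011,IS,SeriesNumber",
    "0020,0013,IS,InstanceNumber",
    "0020,0062,CS,ImageLaterality",
    "0020,4000,LT,ImageComments",
    "0028,0002,US,SamplesPerPixel",
    "0028,0004,CS,PhotometricInterpretation",
    "0028,0010,US,Rows",
    "0028,0011,US,Columns",
    "0028,0100,US,BitsAllocated",
    "0028,0101,US,BitsStored",
    "0028,0102,US,HighBit",
    "0028,0103,US,PixelRepresentation",
    "0038,0010,LO,AdmissionID",
    "0040,0253,SH,PerformedProcedureStepID",
    "0040,1001,SH,RequestedProcedureID",
    "4008,0040,SH,ResultsID",
    "4008,0200,SH,InterpretationID",
    "7FE0,0010,OW,PixelData"
  )
  parts <- do.call(rbind, strsplit(d, ",", fixed = TRUE))
  data.frame(
    group = strtoi(parts[, 1], 16L),
    element = strtoi(parts[, 2], 16L),
    vr = parts[, 3],
    keyword = parts[, 4],
    stringsAsFactors = FALSE
  )
}

.dicom_env <- new.env(parent = emptyenv())

dicom_dict <- function() {
  if (is.null(.dicom_env$dict)) {
    d <- dicom_dictionary()
    d$key <- sprintf("%04X%04X", d$group, d$element)
    .dicom_env$dict <- d
    .dicom_env$by_keyword <- stats::setNames(seq_len(nrow(d)), d$keyword)
    .dicom_env$by_key <- stats::setNames(seq_len(nrow(d)), d$key)
  }
  .dicom_env$dict
}

STRING_VRS <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT", "PN",
                "SH", "ST", "TM", "UC", "UI", "UR", "UT")
LONG_FORM_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")
TRANSFER_SYNTAX_EVRLE <- "1.2.840.10008.1.2.1"
UID_ROOT <- "1.2.826.0.1.3680043.10.1437"

encode_element <- function(group, element, vr, value) {
  tag <- writeBin(as.integer(c(group, element)), raw(), size = 2, endian = "little")
  if (vr %in% STRING_VRS) {
    s <- paste(as.character(value), collapse = "\\")
    payload <- charToRaw(enc2utf8(s))
    if (length(payload) %% 2L == 1L) {
      pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
      payload <- c(payload, pad)
    }
  } else if (vr %in% c("US", "SS")) {
    payload <- writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else if (vr %in% c("UL", "SL")) {
    payload <- writeBin(as.integer(value), raw(), size = 4, endian = "little")
  } else if (vr %in% c("FL")) {
    payload <- writeBin(as.double(value), raw(), size = 4, endian = "little")
  } else if (vr %in% c("FD")) {
    payload <- writeBin(as.double(value), raw(), size = 8, endian = "little")
  } else if (vr %in% c("OB", "OW")) {
    payload <- as.raw(value)
    if (length(payload) %% 2L == 1L) payload <- c(payload, as.raw(0L))
  } else {
    abort(sprintf("unsupported VR '%s' for writing", vr))
  }
  if (vr %in% LONG_FORM_VRS) {
    c(tag, charToRaw(vr), as.raw(c(0L, 0L)),
      writeBin(length(payload), raw(), size = 4, endian = "little"), payload)
  } else {
    c(tag, charToRaw(vr),
      writeBin(length(payload), raw(), size = 2, endian = "little"), payload)
  }
}

#' Write a minimal DICOM Part-10 file
#'
#' Produces an explicit-VR little-endian file with a standard 128-byte
#' preamble, file-meta group, the given dataset elements, and (optionally) a
#' small uncompressed PixelData payload.  Intended for the synthetic fixture
#' generator; it writes only attributes present in the package dictionary
#' plus optional private elements for exercising the private-tag exclusion
#' rule.
#'
#' @param path Output file path.
#' @param tags Named list: dictionary keyword -> value (character/numeric;
#'   vectors become multi-valued elements).
#' @param pixel Optional raw vector or integer vector written as a PixelData
#'   (OW) element after all header elements.
#' @param private Optional named character vector written as private
#'   (odd-group 0x0009) LO elements; names are ignored on read.
#' @return `path`, invisibly.
#' @export
dcm_write <- function(path, tags, pixel = NULL, private = NULL) {
  dict <- dicom_dict()
  unknown <- setdiff(names(tags), dict$keyword)
  if (length(unknown)) abort(paste("unknown DICOM keyword(s):", paste(unknown, collapse = ", ")))
  sop_class <- tags[["SOPClassUID"]] %||% "1.2.840.10008.5.1.4.1.1.1.2"
  sop_instance <- tags[["SOPInstanceUID"]] %||% paste0(UID_ROOT, ".0")

  meta_elems <- c(
    encode_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    encode_element(0x0002, 0x0002, "UI", sop_class),
    encode_element(0x0002, 0x0003, "UI", sop_instance),
    encode_element(0x0002, 0x0010, "UI", TRANSFER_SYNTAX_EVRLE),
    encode_element(0x0002, 0x0012, "UI", paste0(UID_ROOT, ".1"))
  )
  meta <- c(encode_element(0x0002, 0x0000, "UL", length(meta_elems)), meta_elems)

  idx <- .dicom_env$by_keyword[names(tags)]
  ord <- order(dict$group[idx] * 65536 + dict$element[idx])
  body <- raw(0)
  for (i in ord) {
    kw <- names(tags)[i]
    j <- idx[[i]]
    body <- c(body, encode_element(dict$group[j], dict$element[j], dict$vr[j], tags[[kw]]))
  }
  if (!is.null(private)) {
    el <- 0x1000L
    for (v in private) {
      body <- c(body, encode_element(0x0009, el, "LO", v))
      el <- el + 1L
    }
  }
  if (!is.null(pixel)) {
    body <- c(body, encode_element(0x7FE0, 0x0010, "OW", pixel))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  writeBin(c(meta, body), con)
  invisible(path)
}

dicom_parse_error <- function(path, msg) {
  abort(sprintf("cannot parse DICOM file '%s': %s", path, msg),
        class = "mammodb_dicom_parse_error", path = path)
}

decode_string_value <- function(payload, vr) {
  s <- rawToChar(payload[payload != as.raw(0L)])
  Encoding(s) <- "UTF-8"
  s <- sub("[ ]+$", "", s)
  vals <- strsplit(s, "\\", fixed = TRUE)[[1]]
  if (length(vals) == 0L) vals <- ""
  if (vr == "DS") {
    num <- suppressWarnings(as.numeric(vals))
    if (!anyNA(num)) vals <- num
  } else if (vr == "IS") {
    num <- suppressWarnings(as.integer(vals))
    if (!anyNA(num)) vals <- num
  }
  if (length(vals) == 1L) vals <- vals[[1]]
  vals
}

#' Read the header of a DICOM file
#'
#' Parses the file-meta group and dataset of an explicit-VR little-endian
#' DICOM Part-10 file up to — and excluding — the PixelData element, which is
#' never read from disk.  Private (odd-group) tags are skipped.  Values are
#' rendered human-readable: strings trimmed, multi-valued elements as
#' vectors, decimal/integer strings as numbers, short binary VRs decoded.
#'
#' @param path Path to a DICOM file.
#' @return A named list keyed by tag keyword, each element a
#'   `list(vr = , value = )` pair.  Tags absent from the dictionary are keyed
#'   by `"Xggggeeee"` (hex group/element).
#' @export
dcm_read_header <- function(path) {
  if (!file.exists(path)) dicom_parse_error(path, "file does not exist")
  con <- file(path, "rb")
  on.exit(close(con))
  preamble <- readBin(con, "raw", 132L)
  if (length(preamble) < 132L || rawToChar(preamble[129:132]) != "DICM") {
    dicom_parse_error(path, "missing DICM magic marker")
  }
  dict <- dicom_dict()
  by_key <- .dicom_env$by_key
  out <- list()
  repeat {
    hdr <- readBin(con, "raw", 8L)
    if (length(hdr) < 8L) break
    group <- readBin(hdr[1:2], "integer", size = 2, endian = "little", signed = FALSE)
    element <- readBin(hdr[3:4], "integer", size = 2, endian = "little", signed = FALSE)
    vr <- rawToChar(hdr[5:6])
    if (!grepl("^[A-Z]{2}$", vr)) dicom_parse_error(path, "not explicit-VR little-endian")
    if (vr %in% LONG_FORM_VRS) {
      len_raw <- readBin(con, "raw", 4L)
      len <- readBin(len_raw, "integer", size = 4, endian = "little")
      if (len == -1L) dicom_parse_error(path, "undefined-length element unsupported")
    } else {
      len <- readBin(hdr[7:8], "integer", size = 2, endian = "little", signed = FALSE)
    }
    if (group == 0x7FE0 && element == 0x0010) break  # stop before pixel data
    if (group %% 2L == 1L || vr == "SQ") {           # private tag or sequence: skip bytes
      if (len > 0) seek(con, len, origin = "current")
      next
    }
    payload <- if (len > 0) readBin(con, "raw", len) else raw(0)
    if (length(payload) < len) dicom_parse_error(path, "truncated element")
    if (group == 0x0002) {
      if (element == 0x0010) {
        ts <- decode_string_value(payload, "UI")
        if (!identical(ts, TRANSFER_SYNTAX_EVRLE)) {
          dicom_parse_error(path, sprintf("unsupported transfer syntax '%s'", ts))
        }
      }
      next
    }
    key <- sprintf("%04X%04X", group, element)
    j <- by_key[[key]]
    keyword <- if (!is.null(j)) dict$keyword[j] else paste0("X", key)
    value <- if (vr %in% STRING_VRS) {
      decode_string_value(payload, vr)
    } else if (vr %in% c("US", "SS")) {
      readBin(payload, "integer", n = len %/% 2L, size = 2, endian = "little",
              signed = vr == "SS")
    } else if (vr %in% c("UL", "SL")) {
      readBin(payload, "integer", n = len %/% 4L, size = 4, endian = "little")
    } else if (vr == "FL") {
      readBin(payload, "double", n = len %/% 4L, size = 4, endian = "little")
    } else if (vr == "FD") {
      readBin(payload, "double", n = len %/% 8L, size = 8, endian = "little")
    } else {
      next  # other binary VRs: not indexed
    }
    out[[keyword]] <- list(vr = vr, value = value)
  }
  if (length(out) == 0L) dicom_parse_error(path, "no dataset elements found")
  out
}

#' Recursively find DICOM files under a directory
#'
#' Searches `root` at any depth for files whose name ends in `.dcm`
#' (case-insensitive) with no assumption about folder structure; files
#' without the extension are never probed.  The result is sorted so
#' downstream ingestion is deterministic.
#'
#' @param root Existing directory.
#' @return Sorted character vector of file paths.
#' @export
scan_dicom_tree <- function(root) {
  if (!dir.exists(root)) {
    abort(sprintf("root directory '%s' does not exist", root),
          class = "mammodb_path_error")
  }
  paths <- list.files(root, recursive = TRUE, full.names = TRUE)
  sort(paths[grepl("\\.dcm$", paths, ignore.case = TRUE)])
}

# A file qualifies for indexing when it can be identified (SOPInstanceUID)
# and placed in the hierarchy: either by its series/study UIDs or by the
# (PatientID, StudyDate) fallback used for study grouping.
uid_requirement <- function(tags) {
  has <- function(kw) !is.null(tags[[kw]]) && nzchar(as.character(tags[[kw]]$value)[1])
  if (!has("SOPInstanceUID")) return("missing SOPInstanceUID")
  if (has("SeriesInstanceUID") && has("StudyInstanceUID")) return(NULL)
  if (has("PatientID") && has("StudyDate")) return(NULL)
  "missing SeriesInstanceUID/StudyInstanceUID and no (PatientID, StudyDate) fallback"
}

#' Index DICOM headers into the ImageMetadata collection
#'
#' Reads each file's header (never pixel data) and inserts one
#' `ImageMetadata` document per parseable file that satisfies the identity
#' requirement: `SOPInstanceUID` plus either both hierarchy UIDs or the
#' `(PatientID, StudyDate)` fallback.  Files already indexed (same
#' `SOPInstanceUID` within the project) are skipped, so re-running over the
#' same tree is safe; per-file failures are reported, never fatal.  The
#' result is independent of `workers` (headers may be read in parallel, but
#' insertion order follows the sorted path order).
#'
#' @inheritParams ds_insert
#' @param paths File paths, typically from [scan_dicom_tree()].
#' @param workers Number of parallel header readers (>= 1).
#' @return An `ingest_report`: list with `n_ok`, `n_failed`, `n_skipped`, and
#'   a `failures` tibble (`path`, `reason`).
#' @export
ingest_images <- function(store, paths, project, workers = 1L) {
  stopifnot(workers >= 1L)
  ds_register(store, "ImageMetadata")
  paths <- sort(paths)
  read_one <- function(p) {
    tryCatch(list(ok = TRUE, tags = dcm_read_header(p)),
             error = function(e) list(ok = FALSE, reason = conditionMessage(e)))
  }
  headers <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(paths, read_one, mc.cores = workers)
  } else {
    lapply(paths, read_one)
  }
  seen <- new.env(parent = emptyenv())
  for (d in ds_docs(store, "ImageMetadata", project)) {
    assign(d$body$sop_instance_uid, TRUE, envir = seen)
  }
  n_ok <- 0L; n_skipped <- 0L
  fail_path <- character(); fail_reason <- character()
  for (i in seq_along(paths)) {
    h <- headers[[i]]
    if (!h$ok) {
      fail_path <- c(fail_path, paths[i]); fail_reason <- c(fail_reason, h$reason)
      next
    }
    req <- uid_requirement(h$tags)
    if (!is.null(req)) {
      fail_path <- c(fail_path, paths[i]); fail_reason <- c(fail_reason, req)
      next
    }
    uid <- as.character(h$tags$SOPInstanceUID$value)[1]
    if (exists(uid, envir = seen, inherits = FALSE)) {
      n_skipped <- n_skipped + 1L
      next
    }
    assign(uid, TRUE, envir = seen)
    ds_insert(store, "ImageMetadata", list(
      file_path = normalizePath(paths[i], mustWork = FALSE),
      original_file_name = basename(paths[i]),
      sop_instance_uid = uid,
      dicom_tags = h$tags
    ), project)
    n_ok <- n_ok + 1L
  }
  structure(
    list(
      n_ok = n_ok,
      n_failed = length(fail_path),
      n_skipped = n_skipped,
      failures = tibble(path = fail_path, reason = fail_reason)
    ),
    class = "ingest_report"
  )
}

#' @export
print.ingest_report <- function(x, ...) {
  cat("<ingest_report> ok:", x$n_ok, " failed:", x$n_failed,
      " skipped:", x$n_skipped, "\n")
  if (x$n_failed > 0) print(x$failures)
  invisible(x)
}
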