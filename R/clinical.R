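#' Double-reading decision levels
#'
#' The decisions recorded for each screening examination in the radiology
#' information system: two independent radiologist reads and one final
#' (consensus) decision.  `DISCUSSION` marks a read flagged for the
#' consensus discussion; `NA_DECISION` marks a missing decision (common,
#' since not every invited woman participates).
#'
#' @return Character vector of the five decision levels.
#' @export
decision_levels <- function() {
  c("DISCUSSION", "HEALTHY", "SELECTION", "TECHNICAL_RECALL", "NA_DECISION")
}

# Source-string -> Decision mapping used by the default RIS schema.
DECISION_STRINGS <- c(
  "Healthy" = "HEALTHY",
  "Selection" = "SELECTION",
  "Discussion" = "DISCUSSION",
  "Technical recall" = "TECHNICAL_RECALL",
  "N/A" = "NA_DECISION"
)

#' Parse decision source strings
#'
#' Maps the source strings one-to-one onto the decision levels; unknown
#' strings are rejected, never coerced.
#'
#' @param x Character vector of source decision strings.
#' @param mapping Named character vector: source string -> decision level.
#' @return Character vector of decision levels.
#' @export
parse_decision <- function(x, mapping = DECISION_STRINGS) {
  out <- unname(mapping[as.character(x)])
  bad <- is.na(out)
  if (any(bad)) {
    abort(sprintf("unknown decision string(s): %s",
                  paste(unique(x[bad]), collapse = ", ")),
          class = "mammodb_decision_error")
  }
  out
}

#' Read a RIS assessment table in its non-standard dialect
#'
#' The assessment extracts arrive as CSV in a non-standard dialect:
#' Windows-1252 encoded, `$` as the column delimiter, and `£` as the string
#' delimiter.  Each line is decoded from Windows-1252 to UTF-8, then split
#' on `$` outside `£`-quoted spans (a doubled `££` inside a quoted span is
#' an escaped literal `£`).  Undecodable lines are reported, not fatal.
#'
#' @param path File path.
#' @param col_names `TRUE` to treat the first row as a header.
#' @return A tibble of character columns; rows that failed to decode are in
#'   `attr(, "bad_rows")` (line number and reason).
#' @export
read_ris_csv <- function(path, col_names = TRUE) {
  stopifnot(file.exists(path))
  bytes <- readBin(path, "raw", file.info(path)$size)
  nl <- which(bytes == as.raw(0x0A))
  starts <- c(1L, nl + 1L)
  ends <- c(nl, length(bytes) + 1L)
  bad_line <- integer(); bad_reason <- character()
  rows <- list()
  line_no <- 0L
  for (k in seq_along(starts)) {
    if (starts[k] > ends[k] - 1L) next
    chunk <- bytes[starts[k]:(ends[k] - 1L)]
    if (length(chunk) && chunk[length(chunk)] == as.raw(0x0D)) {
      chunk <- chunk[-length(chunk)]
    }
    if (length(chunk) == 0L) next
    line_no <- line_no + 1L
    decoded <- iconv(list(chunk), from = "WINDOWS-1252", to = "UTF-8")
    if (is.na(decoded)) {
      bad_line <- c(bad_line, line_no)
      bad_reason <- c(bad_reason,
                      sprintf("undecodable Windows-1252 byte near offset %d", starts[k]))
      next
    }
    rows[[length(rows) + 1L]] <- split_dialect_line(decoded)
  }
  if (length(rows) == 0L) {
    out <- tibble()
  } else {
    ncol <- max(map_int(rows, length))
    mat <- t(vapply(rows, function(r) c(r, rep(NA_character_, ncol - length(r))),
                    character(ncol)))
    if (isTRUE(col_names)) {
      header <- mat[1, ]
      mat <- mat[-1, , drop = FALSE]
    } else {
      header <- sprintf("V%d", seq_len(ncol))
    }
    out <- as_tibble(as.data.frame(mat, stringsAsFactors = FALSE),
                     .name_repair = "minimal")
    names(out) <- header
  }
  attr(out, "bad_rows") <- tibble(line = bad_line, reason = bad_reason)
  out
}

# State machine over characters: split on the delimiter outside quoted
# spans; a doubled quote inside a span is a literal quote character.
split_dialect_line <- function(line, delim = "$", quote = "£") {
  chars <- strsplit(line, "", fixed = FALSE)[[1]]
  fields <- character()
  buf <- character()
  in_quote <- FALSE
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (in_quote) {
      if (ch == quote) {
        if (i < n && chars[i + 1L] == quote) {
          buf <- c(buf, quote)
          i <- i + 1L
        } else {
          in_quote <- FALSE
        }
      } else {
        buf <- c(buf, ch)
      }
    } else if (ch == quote) {
      in_quote <- TRUE
    } else if (ch == delim) {
      fields <- c(fields, paste(buf, collapse = ""))
      buf <- character()
    } else {
      buf <- c(buf, ch)
    }
    i <- i + 1L
  }
  c(fields, paste(buf, collapse = ""))
}

write_dialect_line <- function(fields, delim = "$", quote = "£") {
  quoted <- vapply(as.character(fields), function(f) {
    paste0(quote, gsub(quote, paste0(quote, quote), f, fixed = TRUE), quote)
  }, character(1), USE.NAMES = FALSE)
  paste(quoted, collapse = delim)
}

#' Collapse a double-reading outcome into a single status
#'
#' The status of an examination is the collapsed *final* decision: healthy,
#' selection, or technical recall map to themselves and a missing final
#' decision stays missing.  This reproduces the observed mapping across all
#' combinations of (first, second, final) decisions present in Swedish
#' screening extracts.  `DISCUSSION` never occurs as a final decision in
#' those combinations; encountering it is treated as a data-quality error
#' rather than silently collapsed.
#'
#' @param final Character vector of final decisions (see
#'   [decision_levels()]).
#' @return Character vector of statuses (`HEALTHY`, `SELECTION`,
#'   `TECHNICAL_RECALL`, `NA_DECISION`).
#' @export
collapse_assessment <- function(final) {
  final <- as.character(final)
  bad <- !final %in% decision_levels()
  if (any(bad)) {
    abort(sprintf("unknown decision(s): %s", paste(unique(final[bad]), collapse = ", ")),
          class = "mammodb_decision_error")
  }
  if (any(final == "DISCUSSION")) {
    abort("DISCUSSION is not a valid final decision",
          class = "mammodb_decision_error")
  }
  final
}

# Round half-up to `digits` decimals (printed summaries use half-up, not
# banker's rounding).
round_half_up <- function(x, digits = 2L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Summarize assessment statuses
#'
#' Counts records per collapsed status and the percentage of the total,
#' rounded half-up to two decimals.  All four statuses are always present
#' in the output (zero counts included), in fixed order.
#'
#' @param records A data frame with a `status` column.
#' @return A tibble with columns `status`, `count`, `percent`.
#' @export
summarize_statuses <- function(records) {
  statuses <- c("HEALTHY", "SELECTION", "TECHNICAL_RECALL", "NA_DECISION")
  counts <- vapply(statuses, function(s) sum(records$status == s), integer(1))
  total <- sum(counts)
  tibble(
    status = statuses,
    count = unname(counts),
    percent = if (total == 0) rep(0, 4L) else round_half_up(100 * unname(counts) / total, 2L)
  )
}

#' Label an examination against the cancer reference standard
#'
#' An examination represents a cancer case iff any diagnosis date falls
#' within the follow-up window after the screening date:
#' `screening_date <= d <= screening_date + follow_up_months`.  The window
#' is calendar-month addition with end-of-month clamping; a diagnosis on
#' the screening day itself counts as within the window (a diagnosis that
#' close is the outcome of the screening itself).  Storing dates rather
#' than labels allows alternative window definitions — a short window (e.g.
#' 3 months) biases toward cancers apparent to the radiologists, a long one
#' (e.g. 36 months) adds uncertainty about whether the cancer was present
#' at screening.
#'
#' @param screening_date A `Date`.
#' @param diagnoses Vector of diagnosis `Date`s (possibly empty).
#' @param follow_up_months Positive integer window length (default 36).
#' @return List with `is_case` (logical) and `matched_diagnosis` (earliest
#'   in-window diagnosis `Date`, or `NULL`).
#' @export
label_reference_standard <- function(screening_date, diagnoses,
                                     follow_up_months = 36L) {
  stopifnot(inherits(screening_date, "Date"), follow_up_months >= 1L)
  diagnoses <- as.Date(diagnoses)
  window_end <- lubridate::`%m+%`(screening_date,
                                  lubridate::period(as.integer(follow_up_months), "months"))
  hit <- diagnoses[!is.na(diagnoses) & diagnoses >= screening_date & diagnoses <= window_end]
  if (length(hit) == 0L) {
    list(is_case = FALSE, matched_diagnosis = NULL)
  } else {
    list(is_case = TRUE, matched_diagnosis = min(hit))
  }
}

#' Default RIS schema
#'
#' Column names are region-specific in real extracts, so the mapping from
#' columns to record fields is configuration.  This default matches the
#' synthetic fixtures.
#'
#' @return Named list mapping record fields to column names, plus the
#'   decision-string mapping.
#' @export
ris_schema_default <- function() {
  list(
    request_number = "request_number",
    person_number = "person_number",
    screening_date = "screening_date",
    first_decision = "first_decision",
    second_decision = "second_decision",
    final_decision = "final_decision",
    decision_strings = DECISION_STRINGS
  )
}

#' Parse RIS rows into assessment records
#'
#' Validates and converts the raw rows of [read_ris_csv()] into one record
#' per double-reading event: decisions parsed onto the closed enumeration,
#' status collapsed from the final decision, screening date parsed, and the
#' personal number validated ([validate_pnr()]) and replaced by its salted
#' digest ([normalize_and_hash_pnr()]) — raw personal numbers never reach
#' the output.  Rows that fail validation are quarantined with a reason.
#'
#' @param rows Tibble from [read_ris_csv()].
#' @param salt Secret salt for personal-number hashing.
#' @param schema Schema as in [ris_schema_default()].
#' @return List with `records` (tibble: `request_number`, `first_decision`,
#'   `second_decision`, `final_decision`, `status`, `screening_date`,
#'   `person_digest`, `pnr_score`) and `quarantined` (tibble: `row`,
#'   `reason`).
#' @export
parse_ris_rows <- function(rows, salt, schema = ris_schema_default()) {
  q_row <- integer(); q_reason <- character()
  recs <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    rec <- tryCatch({
      first <- parse_decision(r[[schema$first_decision]], schema$decision_strings)
      second <- parse_decision(r[[schema$second_decision]], schema$decision_strings)
      final <- parse_decision(r[[schema$final_decision]], schema$decision_strings)
      status <- collapse_assessment(final)
      sdate <- as.Date(r[[schema$screening_date]])
      if (is.na(sdate)) abort("unparseable screening date")
      ph <- normalize_and_hash_pnr(r[[schema$person_number]], salt)
      tibble(
        request_number = as.character(r[[schema$request_number]]),
        first_decision = first, second_decision = second,
        final_decision = final, status = status,
        screening_date = sdate,
        person_digest = ph$digest, pnr_score = ph$score$score
      )
    }, error = function(e) {
      q_row <<- c(q_row, i); q_reason <<- c(q_reason, conditionMessage(e))
      NULL
    })
    recs[[i]] <- rec
  }
  records <- bind_rows(compact(recs))
  if (nrow(records) > 0 && anyDuplicated(records$request_number)) {
    dup <- records$request_number[duplicated(records$request_number)]
    warn(sprintf("duplicate request number(s): %s", paste(unique(dup), collapse = ", ")))
  }
  list(records = records, quarantined = tibble(row = q_row, reason = q_reason))
}

#' Default registry (outcome table) schema
#'
#' Describes how each registry column is parsed: its target field, type, and
#' — for enumerations — the closed code mapping.  The enumerations double as
#' documentation and validation: values outside them quarantine the row.
#' The shipped default mirrors the national breast-cancer registry layout
#' used by the synthetic fixtures, including the `a_pat_sida` laterality
#' column with codes `1` (right) and `2` (left).
#'
#' @return Named list of column specifications.
#' @export
nkbc_schema_default <- function() {
  list(
    pnr = list(field = "person_number", type = "pnr"),
    a_diag_dat = list(field = "diagnosis_date", type = "date"),
    a_pat_sida = list(field = "laterality", type = "enum",
                      levels = c("1" = "right", "2" = "left")),
    a_stud_id = list(field = "study_ref", type = "string", optional = TRUE),
    a_tum_storlek = list(field = "tumor_size_mm", type = "number", optional = TRUE)
  )
}

#' Read and validate a registry outcome table
#'
#' Parses a UTF-8 comma-separated outcome extract row by row against the
#' schema: typed columns are converted, enumeration columns validated
#' against their closed code sets, the diagnosis date checked against the
#' configured registry era, and the personal number validated and hashed
#' before storage.  The full original row (minus the raw personal number)
#' is retained under `original_row` for audit.  Invalid rows are
#' quarantined with a reason; parsed and quarantined counts always sum to
#' the number of input rows.
#'
#' @param path CSV file path.
#' @param salt Secret salt for personal-number hashing.
#' @param schema Column specification as in [nkbc_schema_default()].
#' @param era Two `Date`s bounding plausible diagnosis dates.
#' @return List with `records` (tibble: `person_digest`, `pnr_score`,
#'   `diagnosis_date`, `laterality`, other schema fields, `original_row`
#'   list-column) and `quarantined` (tibble: `row`, `reason`).
#' @export
read_nkbc_csv <- function(path, salt, schema = nkbc_schema_default(),
                          era = as.Date(c("2008-01-01", "2021-12-31"))) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         encoding = "UTF-8")
  q_row <- integer(); q_reason <- character()
  recs <- vector("list", nrow(raw))
  pnr_col <- names(schema)[map_chr(schema, "type") == "pnr"][1]
  for (i in seq_len(nrow(raw))) {
    r <- raw[i, , drop = FALSE]
    rec <- tryCatch({
      fields <- list()
      for (col in names(schema)) {
        sp <- schema[[col]]
        v <- if (col %in% names(r)) r[[col]] else NA_character_
        if (is.na(v) || !nzchar(v)) {
          if (isTRUE(sp$optional)) next
          abort(sprintf("missing required column '%s'", col))
        }
        fields[[sp$field]] <- switch(sp$type,
          pnr = v,
          date = {
            d <- as.Date(v)
            if (is.na(d)) abort(sprintf("unparseable date '%s' in '%s'", v, col))
            if (d < era[1] || d > era[2]) {
              abort(sprintf("date '%s' outside registry era", v))
            }
            d
          },
          enum = {
            if (!v %in% names(sp$levels)) {
              abort(sprintf("value '%s' not in enumeration for '%s'", v, col))
            }
            unname(sp$levels[[v]])
          },
          number = {
            num <- suppressWarnings(as.numeric(v))
            if (is.na(num)) abort(sprintf("non-numeric '%s' in '%s'", v, col))
            num
          },
          string = as.character(v)
        )
      }
      ph <- normalize_and_hash_pnr(fields$person_number, salt)
      fields$person_number <- NULL
      orig <- as.list(r)
      orig[[pnr_col]] <- NULL  # raw personal number never stored
      out <- tibble(person_digest = ph$digest, pnr_score = ph$score$score)
      for (nm in names(fields)) out[[nm]] <- fields[[nm]]
      out$original_row <- list(orig)
      out
    }, error = function(e) {
      q_row <<- c(q_row, i); q_reason <<- c(q_reason, conditionMessage(e))
      NULL
    })
    recs[[i]] <- rec
  }
  list(records = bind_rows(compact(recs)),
       quarantined = tibble(row = q_row, reason = q_reason))
}

#' Load assessments or outcomes into the store
#'
#' Thin store-persisting wrappers: each validated record becomes one
#' `RISRecord` / `NKBCRecord` document; quarantine reports are returned.
#'
#' @inheritParams ds_insert
#' @param path Source file path.
#' @param salt Secret salt string.
#' @param schema Schema (see [ris_schema_default()], [nkbc_schema_default()]).
#' @return The parse result (records + quarantined), invisibly.
#' @export
load_ris <- function(store, path, project, salt, schema = ris_schema_default()) {
  ds_register(store, "RISRecord")
  parsed <- parse_ris_rows(read_ris_csv(path), salt, schema)
  for (i in seq_len(nrow(parsed$records))) {
    rec <- as.list(parsed$records[i, ])
    rec$screening_date <- format(rec$screening_date)
    ds_insert(store, "RISRecord", rec, project)
  }
  invisible(parsed)
}

#' @rdname load_ris
#' @param era Plausible diagnosis-date bounds.
#' @export
load_nkbc <- function(store, path, project, salt, schema = nkbc_schema_default(),
                      era = as.Date(c("2008-01-01", "2021-12-31"))) {
  ds_register(store, "NKBCRecord")
  parsed <- read_nkbc_csv(path, salt, schema, era)
  for (i in seq_len(nrow(parsed$records))) {
    rec <- as.list(parsed$records[i, ])
    rec$diagnosis_date <- format(rec$diagnosis_date)
    rec$original_row <- rec$original_row[[1]]
    ds_insert(store, "NKBCRecord", rec, project)
  }
  invisible(parsed)
}
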