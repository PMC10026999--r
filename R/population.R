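#' Case-control selection configuration
#'
#' @param control_ratio Target controls per case participant within each
#'   stratum (default 5, i.e. a 1:5 case-to-control ratio).
#' @param case_window_months A case participant's exams are those acquired
#'   within this many months *before* her diagnosis (default 36).
#' @param age_bin_years Width of the age bins used for balancing (default 5,
#'   matching the characteristic binning used at pseudonymization).
#' @param seed Integer seed; selection is deterministic given the seed, and
#'   the seed is recorded on the resulting selection list.
#' @return An object of class `cc_config`.
#' @export
cc_config <- function(control_ratio = 5, case_window_months = 36L,
                      age_bin_years = 5L, seed = 1L) {
  stopifnot(control_ratio > 0, case_window_months >= 1L, age_bin_years >= 1L)
  structure(list(control_ratio = control_ratio,
                 case_window_months = as.integer(case_window_months),
                 age_bin_years = as.integer(age_bin_years),
                 seed = as.integer(seed)),
            class = "cc_config")
}

age_bin <- function(age, width) {
  sprintf("%02d-%02d", (age %/% width) * width, (age %/% width) * width + width - 1L)
}

#' Select a case-control population
#'
#' Cases are all participants present in the outcomes data; each case
#' contributes her exams acquired within `case_window_months` before the
#' (earliest) diagnosis.  Controls are a seeded random sample of
#' participants who are *not* in the outcomes data and have at least one
#' assessment record, drawn per stratum of examination year and age bin at
#' approximately `control_ratio` control participants per case participant,
#' so the sample is balanced for age and examination year.  A selected
#' control contributes all her exams.  A person appears in at most one arm;
#' a stratum with too few eligible controls takes all of them and flags the
#' shortfall (never sampling with replacement).
#'
#' @param exams Tibble with columns `person_digest`, `exam_id`, `exam_date`
#'   (`Date`), `age` (years at exam).
#' @param outcomes Tibble with columns `person_digest`, `diagnosis_date`
#'   (`Date`).
#' @param assessments Tibble with a `person_digest` column; control
#'   eligibility requires at least one assessment record.
#' @param config A [cc_config()].
#' @return A `selection_list`: `population_name`, `members` tibble
#'   (`person_digest`, `exam_id`, `arm`, `stratum`), `counts`, `shortfall`
#'   tibble, and the seed.
#' @export
select_case_control <- function(exams, outcomes, assessments, config = cc_config()) {
  stopifnot(inherits(config, "cc_config"))
  first_dx <- if (nrow(outcomes) == 0L) {
    tibble(person_digest = character(), diagnosis_date = as.Date(character()))
  } else {
    outcomes |>
      group_by(.data$person_digest) |>
      summarise(diagnosis_date = min(.data$diagnosis_date), .groups = "drop")
  }

  case_exams <- exams |>
    dplyr::inner_join(first_dx, by = "person_digest") |>
    filter(.data$exam_date <= .data$diagnosis_date,
           .data$exam_date >= lubridate::`%m-%`(
             .data$diagnosis_date,
             lubridate::period(config$case_window_months, "months"))) |>
    mutate(
      stratum = paste0(lubridate::year(.data$exam_date), "/",
                       age_bin(.data$age, config$age_bin_years)),
      arm = "case"
    ) |>
    select("person_digest", "exam_id", "arm", "stratum")

  # Stratum targets: ratio x distinct case participants, per (year, age bin).
  targets <- case_exams |>
    distinct(.data$person_digest, .data$stratum) |>
    count(.data$stratum, name = "n_cases") |>
    mutate(n_target = as.integer(round_half_up(config$control_ratio * .data$n_cases, 0L)))

  eligible <- exams |>
    anti_join(outcomes, by = "person_digest") |>
    semi_join(distinct(assessments, .data$person_digest), by = "person_digest") |>
    mutate(stratum = paste0(lubridate::year(.data$exam_date), "/",
                            age_bin(.data$age, config$age_bin_years)))

  chosen <- character()
  short_stratum <- character(); short_by <- integer()
  control_members <- list()
  set.seed(config$seed)
  for (i in order(targets$stratum)) {
    st <- targets$stratum[i]
    pool <- eligible |>
      filter(.data$stratum == st, !.data$person_digest %in% chosen) |>
      distinct(.data$person_digest) |>
      pull("person_digest") |>
      sort()
    n_take <- targets$n_target[i]
    if (length(pool) < n_take) {
      short_stratum <- c(short_stratum, st)
      short_by <- c(short_by, n_take - length(pool))
      take <- pool
    } else {
      take <- sample(pool, n_take)
    }
    chosen <- c(chosen, take)
    control_members[[st]] <- tibble(person_digest = take, stratum = st)
  }
  control_participants <- bind_rows(
    c(list(tibble(person_digest = character(), stratum = character())),
      control_members)
  )
  control_exams <- exams |>
    semi_join(control_participants, by = "person_digest") |>
    left_join(select(control_participants, "person_digest", "stratum"),
              by = "person_digest") |>
    mutate(arm = "control") |>
    select("person_digest", "exam_id", "arm", "stratum")

  members <- bind_rows(case_exams, control_exams) |>
    arrange(.data$arm, .data$stratum, .data$person_digest, .data$exam_id)

  structure(list(
    population_name = "case-control",
    members = members,
    counts = list(
      case_participants = dplyr::n_distinct(case_exams$person_digest),
      case_exams = nrow(case_exams),
      control_participants = dplyr::n_distinct(control_exams$person_digest),
      control_exams = nrow(control_exams)
    ),
    shortfall = tibble(stratum = short_stratum, missing = short_by),
    seed = config$seed
  ), class = "selection_list")
}

#' Select a cohort population
#'
#' Takes every exam acquired in the given calendar year and labels each as
#' a cohort case (diagnosed within the follow-up window after the exam) or
#' cohort control (not diagnosed within it) via
#' [label_reference_standard()].  Cases and controls partition the year's
#' exams exactly.
#'
#' @inheritParams select_case_control
#' @param year Calendar year of acquisition.
#' @param window_months Follow-up window in months (default 36).
#' @return A `selection_list` (see [select_case_control()]); `stratum` is
#'   the cohort year.
#' @export
select_cohort <- function(exams, outcomes, year, window_months = 36L) {
  year_exams <- filter(exams, lubridate::year(.data$exam_date) == year)
  dx_by_person <- split(outcomes$diagnosis_date, outcomes$person_digest)
  arm <- vapply(seq_len(nrow(year_exams)), function(i) {
    dx <- dx_by_person[[year_exams$person_digest[i]]]
    if (is.null(dx)) return("control")
    lab <- label_reference_standard(year_exams$exam_date[i], dx, window_months)
    if (lab$is_case) "case" else "control"
  }, character(1))
  members <- year_exams |>
    mutate(arm = arm, stratum = as.character(year)) |>
    select("person_digest", "exam_id", "arm", "stratum") |>
    arrange(.data$arm, .data$person_digest, .data$exam_id)
  structure(list(
    population_name = sprintf("cohort-%d", as.integer(year)),
    members = members,
    counts = list(
      case_participants = dplyr::n_distinct(members$person_digest[members$arm == "case"]),
      case_exams = sum(members$arm == "case"),
      control_participants = dplyr::n_distinct(members$person_digest[members$arm == "control"]),
      control_exams = sum(members$arm == "control")
    ),
    shortfall = tibble(stratum = character(), missing = integer()),
    seed = NA_integer_
  ), class = "selection_list")
}

#' @export
print.selection_list <- function(x, ...) {
  cat("<selection_list>", x$population_name, "\n")
  cat("  cases:   ", x$counts$case_participants, "participants,",
      x$counts$case_exams, "exams\n")
  cat("  controls:", x$counts$control_participants, "participants,",
      x$counts$control_exams, "exams\n")
  if (nrow(x$shortfall)) cat("  shortfall in", nrow(x$shortfall), "stratum/strata\n")
  invisible(x)
}

#' Write a selection list as CSV
#'
#' Two dialects of the same list: the digest-bearing form
#' (`pseudonymized = TRUE`, verification-bound) contains only 64-hex
#' person digests, while the identifier-bearing form (hospital-bound, for
#' retrieving the actual images) requires a reversible `id_map` from a
#' protected side store and writes original identifiers instead.
#'
#' @param selection A `selection_list`.
#' @param path Output CSV path (UTF-8, comma-separated, header
#'   `person_id,exam_id,arm,stratum`).
#' @param pseudonymized Write digests (`TRUE`) or original identifiers
#'   (`FALSE`, requires `id_map`).
#' @param id_map Named character vector digest -> original identifier.
#' @return `path`, invisibly.
#' @export
emit_selection <- function(selection, path, pseudonymized = TRUE, id_map = NULL) {
  stopifnot(inherits(selection, "selection_list"))
  members <- selection$members
  if (!pseudonymized) {
    if (is.null(id_map)) {
      abort("an id_map is required to emit an identifier-bearing list",
            class = "mammodb_idmap_error")
    }
    ids <- unname(id_map[members$person_digest])
    if (anyNA(ids)) abort("id_map lacks entries for some selected digests",
                          class = "mammodb_idmap_error")
    members$person_digest <- ids
  }
  out <- members
  names(out)[names(out) == "person_digest"] <- "person_id"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back an emitted selection list
#'
#' @param path CSV written by [emit_selection()].
#' @return Tibble with columns `person_id`, `exam_id`, `arm`, `stratum`.
#' @export
read_selection <- function(path) {
  as_tibble(utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8"))
}
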