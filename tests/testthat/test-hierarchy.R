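test_that("shared-tag merge keeps agreement, drops conflict, votes on missing", {
  expect_equal(merge_tags_iamm(list(list(A = te(1)))), list(A = te(1)))
  expect_equal(merge_tags_iamm(list(list(A = te(1)), list(A = te(2)))), list())
  # missing in a minority: kept; missing in a majority: dropped
  expect_equal(merge_tags_iamm(list(list(A = te(1)), list(A = te(1)), list())),
               list(A = te(1)))
  expect_equal(merge_tags_iamm(list(list(A = te(1)), list(), list())), list())
  # tie (present in exactly half) is not a strict majority
  expect_equal(merge_tags_iamm(list(list(A = te(1)), list())), list())
  expect_error(merge_tags_iamm(list()), "non-empty")
})

test_that("shared-tag merge matches the brute-force vote oracle and its invariants", {
  withr::with_seed(202, {
    for (rep in 1:300) {
      maps <- random_tag_maps(sample(1:7, 1))
      got <- merge_tags_iamm(maps)
      expect_equal(sort_by_name(got), sort_by_name(iamm_oracle(maps)),
                   info = sprintf("case %d", rep))
      # permutation invariance
      perm <- sample(length(maps))
      expect_equal(sort_by_name(got), sort_by_name(merge_tags_iamm(maps[perm])))
      # output keys subset of input keys; kept values verbatim where present
      expect_true(all(names(got) %in% unique(unlist(lapply(maps, names)))))
      for (k in names(got)) {
        for (m in maps) {
          if (!is.null(m[[k]])) expect_identical(m[[k]], got[[k]])
        }
      }
    }
  })
})

test_that("study datetime promotion parses, defaults to midnight, rejects nonsense", {
  expect_equal(parse_study_datetime("20170115", "093000"), "2017-01-15T09:30:00")
  expect_equal(parse_study_datetime("20170115"), "2017-01-15T00:00:00")
  expect_equal(parse_study_datetime("20170115", "093000.123456"), "2017-01-15T09:30:00")
  expect_error(parse_study_datetime("20171315", "000000"),
               class = "mammodb_promotion_error")  # month 13
  expect_error(parse_study_datetime("2017011"), class = "mammodb_promotion_error")
  # independent check against base R's calendar parser
  iso <- parse_study_datetime("20160229", "235959")
  expect_equal(as.POSIXct(iso, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               as.POSIXct("2016-02-29 23:59:59", tz = "UTC"))
})

make_image <- function(store, project, uid, series, patient, date, extra = list()) {
  tags <- c(list(
    SOPInstanceUID = te(uid, "UI"),
    SeriesInstanceUID = te(series, "UI"),
    StudyInstanceUID = te(paste0("st.", series), "UI"),
    PatientID = te(patient),
    StudyDate = te(date, "DA"),
    Modality = te("MG", "CS")
  ), extra)
  ds_insert(store, "ImageMetadata",
            list(sop_instance_uid = uid, dicom_tags = tags), project)
}

test_that("series are built per UID with merged tags, back-links, idempotence", {
  store <- doc_store()
  ds_register(store, "ImageMetadata")
  make_image(store, "p", "i1", "S1", "P1", "20170101",
             list(Manufacturer = te("Acme")))
  make_image(store, "p", "i2", "S1", "P1", "20170101",
             list(Manufacturer = te("Acme")))
  make_image(store, "p", "i3", "S1", "P1", "20170101")  # Manufacturer missing in 1 of 3
  make_image(store, "p", "i4", "S2", "P1", "20170101")
  ds_insert(store, "ImageMetadata", list(sop_instance_uid = "i5"), "p")  # no series UID

  rep <- build_series(store, "p")
  expect_equal(rep$n_created, 2L)
  expect_length(rep$missing_key_ids, 1L)

  series <- ds_docs(store, "RadiologicalSeries")
  s1 <- purrr::keep(series, function(d) d$body$series_uid == "S1")[[1]]
  expect_equal(s1$body$image_count, 3L)
  expect_equal(s1$body$dicom_tags$Manufacturer$value, "Acme")  # 2-of-3 majority kept
  for (iid in unlist(s1$body$image_ids)) {
    expect_equal(ds_get(store, "ImageMetadata", iid)$body$series_id, s1$id)
  }
  rep2 <- build_series(store, "p")
  expect_equal(rep2$n_created, 0L)
  expect_equal(rep2$n_skipped, 2L)
})

test_that("studies group by patient and date with promoted unions", {
  store <- doc_store()
  ds_register(store, "ImageMetadata")
  make_image(store, "p", "i1", "A1", "P1", "20170101",
             list(StudyTime = te("083000", "TM")))
  make_image(store, "p", "i2", "A2", "P1", "20170101",
             list(StudyTime = te("083000", "TM")))  # different StudyInstanceUID, same study
  make_image(store, "p", "i3", "B1", "P1", "20170601")
  make_image(store, "p", "i4", "B1", "P1", "20170601")

  rep <- build_studies(store, "p")
  expect_equal(rep$n_created, 2L)
  studies <- ds_docs(store, "RadiologicalStudy")
  jan <- purrr::keep(studies, function(d) d$body$study_date_raw == "20170101")[[1]]
  expect_equal(jan$body$date, "2017-01-01T08:30:00")
  expect_equal(sort(unlist(jan$body$study_uid)), c("st.A1", "st.A2"))  # 2-element union
  expect_equal(unlist(jan$body$modality), "MG")
  # countable by promoted modality, like countDocuments({modality:'MG'})
  n_mg <- length(ds_find(store, "RadiologicalStudy",
                         function(d) "MG" %in% unlist(d$body$modality)))
  expect_equal(n_mg, 2L)
  for (iid in unlist(jan$body$image_ids)) {
    expect_equal(ds_get(store, "ImageMetadata", iid)$body$study_id, jan$id)
  }
  expect_equal(build_studies(store, "p")$n_created, 0L)
})

test_that("patients group studies with consistent back-links (re-scan oracle)", {
  store <- doc_store()
  ds_register(store, "ImageMetadata")
  make_image(store, "p", "i1", "S1", "P1", "20170101")
  make_image(store, "p", "i2", "S2", "P1", "20180101")
  make_image(store, "p", "i3", "S3", "P2", "20170301")
  build_studies(store, "p")
  rep <- build_patients(store, "p")
  expect_equal(rep$n_created, 2L)

  pats <- ds_docs(store, "Patient")
  sizes <- unname(sort(vapply(pats, function(d) length(d$body$study_ids), integer(1))))
  expect_equal(sizes, c(1L, 2L))
  for (d in pats) {
    # oracle: independently re-scan studies for this patient id
    expected <- names(ds_find(store, "RadiologicalStudy", function(s) {
      s$body$patient_pseudo_id == d$body$patient_pseudo_id
    }))
    expect_setequal(unlist(d$body$study_ids), expected)
    for (sid in unlist(d$body$study_ids)) {
      expect_equal(ds_get(store, "RadiologicalStudy", sid)$body$patient_id, d$id)
    }
  }
  expect_equal(build_patients(store, "p")$n_created, 0L)
})
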