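test_that("instances qualify on laterality, view and SOP class with ranking", {
  images <- tibble::tibble(
    image_id = c("a", "b", "c", "d", "e"),
    laterality = c("R", "L", "R", "B", "R"),
    view = c("MLO", "CC", "XCCL", "MLO", "MLO"),
    sop_class_uid = c("1.2.840.10008.5.1.4.1.1.1.2",
                      "1.2.840.10008.5.1.4.1.1.1.2.1",
                      "1.2.840.10008.5.1.4.1.1.1.2",
                      "1.2.840.10008.5.1.4.1.1.1",
                      "1.2.840.10008.5.1.4.1.1.4"),  # MR storage: not accepted
    acquisition_time = c("090000", NA, "091000", "092000", "093000"),
    instance_number = 1:5
  )
  q <- qualify_images(images)
  expect_setequal(q$qualified$image_id, c("a", "b"))
  expect_equal(q$qualified$sop_class_rank[q$qualified$image_id == "a"], 0L)
  expect_equal(q$qualified$sop_class_rank[q$qualified$image_id == "b"], 1L)
  expect_setequal(q$rejected$image_id, c("c", "d", "e"))
  expect_match(q$rejected$reason[q$rejected$image_id == "c"], "XCCL")
  expect_match(q$rejected$reason[q$rejected$image_id == "d"], "laterality")
  expect_match(q$rejected$reason[q$rejected$image_id == "e"], "SOP class")
})

test_that("input-case classification matches the truth table over all 81 patterns", {
  patterns <- expand.grid(0:2, 0:2, 0:2, 0:2)
  for (i in seq_len(nrow(patterns))) {
    occ <- as.integer(patterns[i, ])
    truth <- input_case_truth(occ)
    got <- classify_input_case(qualified_from_occupancy(occ))
    expect_equal(got$cases, truth$cases, info = paste(occ, collapse = ","))
    expect_equal(vapply(got$input_sets, length, integer(1)),
                 truth$set_sizes, info = paste(occ, collapse = ","))
    # four-instance sets exactly for cases 1 and 2a/2b, fewer otherwise
    if (length(truth$cases) && truth$cases[1] %in% c("CASE_1", "CASE_2A")) {
      expect_true(all(lengths(got$input_sets) == 4L))
    } else if (length(truth$cases)) {
      expect_true(all(lengths(got$input_sets) < 4L))
    }
    # every selected instance occupies a distinct slot
    for (set in got$input_sets) {
      q <- qualified_from_occupancy(occ)
      expect_equal(anyDuplicated(q$slot[match(set, q$image_id)]), 0L)
    }
  }
})

test_that("newest/oldest sets differ only in multiply-occupied slots", {
  # two R-CC instances, one everywhere else
  q <- qualified_from_occupancy(c(1L, 1L, 2L, 1L))
  got <- classify_input_case(q)
  expect_equal(got$cases, c("CASE_2A", "CASE_2B"))
  only_diff <- setdiff(union(got$input_sets[[1]], got$input_sets[[2]]),
                       intersect(got$input_sets[[1]], got$input_sets[[2]]))
  expect_setequal(q$slot[match(only_diff, q$image_id)], "R-CC")

  # identical ordering keys in the duplicated slot: the UID tiebreak still
  # yields a deterministic, reproducible pair of sets
  q$acquisition_time <- "090000"
  q$instance_number <- 1L
  got2 <- classify_input_case(q)
  expect_identical(got2, classify_input_case(q[sample(nrow(q)), ]))
})

test_that("instance-number ordering is the fallback when acquisition time is absent", {
  q <- tibble::tibble(
    image_id = c("young", "old"), slot = "R-MLO",
    acquisition_time = NA_character_, instance_number = c(7L, 2L),
    sop_class_rank = 0L
  )
  q <- dplyr::bind_rows(q, qualified_from_occupancy(c(0L, 1L, 1L, 1L)))
  got <- classify_input_case(q)
  newest <- got$input_sets[[1]]; oldest <- got$input_sets[[2]]
  expect_true("young" %in% newest)
  expect_true("old" %in% oldest)
})

test_that("score reduction takes per-side maxima, sparsely", {
  expect_equal(
    reduce_scores(list(list(laterality = "R", score = 0.2),
                       list(laterality = "R", score = 0.5),
                       list(laterality = "L", score = 0.1))),
    list(R = 0.5, L = 0.1)
  )
  expect_equal(reduce_scores(list(list(laterality = "L", score = 0.3))), list(L = 0.3))
  expect_equal(reduce_scores(list()), list())

  # idempotent and permutation-invariant
  withr::with_seed(8, {
    sc <- tibble::tibble(laterality = sample(c("R", "L"), 20, replace = TRUE),
                         score = runif(20))
  })
  once <- reduce_scores(sc)
  expect_equal(reduce_scores(sc[sample(nrow(sc)), ]), once)
  again <- reduce_scores(tibble::tibble(laterality = names(once),
                                        score = unlist(once)))
  expect_equal(again[order(names(again))], once[order(names(once))])
})

test_that("vendor payloads normalize across all three dialects", {
  # per-image JSON: maxima per laterality
  payload <- list(study_uid = "1.2.3",
                  results = list(
                    list(image_uid = "a", laterality = "R", score = 0.2),
                    list(image_uid = "b", laterality = "R", score = 0.5),
                    list(image_uid = "c", laterality = "L", score = 0.1)))
  r <- parse_vendor_result(payload, vendor_profile("imagewise_json"))
  expect_equal(r$scores_by_laterality, list(R = 0.5, L = 0.1))
  expect_equal(r$study_ref, "1.2.3")
  expect_equal(nrow(r$per_image_scores), 3L)

  # per-laterality JSON: embedded encoded image stripped from original_data
  payload2 <- list(study_uid = "1.2.4",
                   scores = list(right = 0.7, left = 0.2),
                   overlay_png = "aGVsbG8=",
                   nested = list(overlay_png = "ZGVlcA=="))
  r2 <- parse_vendor_result(payload2, vendor_profile("sidewise_json"))
  expect_equal(r2$scores_by_laterality, list(R = 0.7, L = 0.2))
  expect_null(r2$original_data$overlay_png)
  expect_null(r2$original_data$nested$overlay_png)  # stripped recursively

  # single-laterality payload: other side absent, not null
  payload3 <- list(study_uid = "1.2.5", scores = list(right = 0.9))
  r3 <- parse_vendor_result(payload3, vendor_profile("sidewise_json"))
  expect_equal(names(r3$scores_by_laterality), "R")

  # missing score fields name the path; unknown vendor is a registry error
  expect_error(parse_vendor_result(list(study_uid = "x"), vendor_profile("sidewise_json")),
               class = "mammodb_parse_error")
  err <- tryCatch(parse_vendor_result(list(study_uid = "x", results = list(list(score = 1))),
                                      vendor_profile("imagewise_json")),
                  error = function(e) e)
  expect_match(conditionMessage(err), "laterality")
  expect_error(vendor_profile("acme"), class = "mammodb_registry_error")
})

test_that("the DICOM-dataset dialect round-trips through a written payload", {
  world <- generate_world(fixture_config(n_patients = 2L, seed = 13L))
  d <- withr::local_tempdir()
  prof <- vendor_profile("dataset_dicom")
  n <- emit_vendor_payloads(world, prof, d)
  files <- list.files(d, "\\.dcm$", full.names = TRUE)
  expect_length(files, n)
  r <- parse_vendor_result(files[1], prof)
  expect_true(all(names(r$scores_by_laterality) %in% c("R", "L")))
  # normalized maxima match a brute-force per-side maximum over the payload
  per_img <- r$per_image_scores
  for (side in names(r$scores_by_laterality)) {
    expect_equal(r$scores_by_laterality[[side]],
                 max(per_img$score[per_img$laterality == side]))
  }
})

test_that("capability planning submits whole sets or singletons", {
  sets <- list(c("a", "b", "c", "d"), c("e", "f"))
  four <- vendor_profile("imagewise_json")
  expect_identical(plan_inference_inputs(four, sets), sets)
  single_only <- four
  single_only$capabilities$four_view <- FALSE
  expect_equal(lengths(plan_inference_inputs(single_only, sets)), rep(1L, 6L))
  none <- four
  none$capabilities$four_view <- FALSE; none$capabilities$single <- FALSE
  expect_equal(plan_inference_inputs(none, sets), list())
})
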