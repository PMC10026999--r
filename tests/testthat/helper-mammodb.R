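# Shared helpers: independent oracles and small constructors.  Oracles are
# written independently of the package implementation they check.

# A tag entry as stored in dicom_tags mappings.
te <- function(value, vr = "LO") list(vr = vr, value = value)

sort_by_name <- function(x) if (length(x)) x[order(names(x))] else x

# Brute-force per-tag vote oracle for the shared-tag merge: for every key,
# tally the serialized present values; keep the key iff exactly one distinct
# value occurs and the key is present in a strict majority of the maps.
iamm_oracle <- function(tag_maps) {
  n <- length(tag_maps)
  all_keys <- unique(unlist(lapply(tag_maps, names)))
  out <- list()
  for (k in all_keys) {
    serialized <- character()
    raw_vals <- list()
    for (m in tag_maps) {
      if (!is.null(m[[k]])) {
        serialized <- c(serialized, paste(deparse(m[[k]]), collapse = ""))
        raw_vals[[length(raw_vals) + 1L]] <- m[[k]]
      }
    }
    votes <- table(serialized)
    if (length(votes) == 1L && length(serialized) > n / 2) {
      out[[k]] <- raw_vals[[1]]
    }
  }
  out
}

# Independent Luhn oracle: concatenate the doubled/undoubled digits into one
# string and sum its characters (a different mechanism than the package's
# quotient/remainder arithmetic).
luhn_oracle_valid <- function(digits10) {
  d <- as.integer(strsplit(digits10, "")[[1]])
  if (length(d) != 10L || anyNA(d)) return(FALSE)
  parts <- character()
  for (i in seq_len(9L)) {
    parts <- c(parts, as.character(if (i %% 2L == 1L) d[i] * 2L else d[i]))
  }
  digit_sum <- sum(as.integer(strsplit(paste(parts, collapse = ""), "")[[1]]))
  ((10L - digit_sum %% 10L) %% 10L) == d[10L]
}

luhn_oracle_check_digit <- function(digits9) {
  for (cd in 0:9) {
    if (luhn_oracle_valid(paste0(digits9, cd))) return(cd)
  }
  stop("no check digit found")
}

# Random tag-map list for merge properties: keys A..G, integer values, each
# key present in each map with probability p_present.
random_tag_maps <- function(n_maps, p_present = 0.6, n_keys = 7L, conflict_rate = 0.3) {
  keys <- LETTERS[seq_len(n_keys)]
  vals <- stats::setNames(sample(1:3, n_keys, replace = TRUE), keys)
  lapply(seq_len(n_maps), function(i) {
    m <- list()
    for (k in keys) {
      if (stats::runif(1) < p_present) {
        v <- if (stats::runif(1) < conflict_rate) sample(1:3, 1L) else vals[[k]]
        m[[k]] <- te(v)
      }
    }
    m
  })
}

# Hand-coded truth table for input-case classification from a per-slot
# occupancy pattern (0, 1 or >=2 instances for each of the four view slots).
input_case_truth <- function(occ) {
  if (all(occ == 0L)) {
    return(list(cases = character(), set_sizes = integer()))
  }
  n_present <- sum(occ > 0L)
  if (all(occ >= 1L)) {
    if (all(occ == 1L)) list(cases = "CASE_1", set_sizes = 4L)
    else list(cases = c("CASE_2A", "CASE_2B"), set_sizes = c(4L, 4L))
  } else {
    if (all(occ[occ > 0L] == 1L)) list(cases = "CASE_3", set_sizes = n_present)
    else list(cases = c("CASE_4A", "CASE_4B"), set_sizes = c(n_present, n_present))
  }
}

# Build a qualified-instances tibble realizing an occupancy pattern.
qualified_from_occupancy <- function(occ, slots = c("R-MLO", "L-MLO", "R-CC", "L-CC")) {
  rows <- list()
  idx <- 0L
  for (s in seq_along(slots)) {
    for (r in seq_len(occ[s])) {
      idx <- idx + 1L
      rows[[idx]] <- tibble::tibble(
        image_id = sprintf("img%02d", idx), slot = slots[s],
        acquisition_time = sprintf("%06d", 90000L + idx),
        instance_number = idx, sop_class_rank = 0L
      )
    }
  }
  if (idx == 0L) {
    tibble::tibble(image_id = character(), slot = character(),
                   acquisition_time = character(), instance_number = integer(),
                   sop_class_rank = integer())
  } else {
    dplyr::bind_rows(rows)
  }
}

run_python <- function(code) {
  f <- tempfile(fileext = ".py")
  writeLines(code, f)
  out <- system2("python", f, stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("python oracle failed: ", paste(out, collapse = "\n"))
  }
  out
}

# A small fully ingested store used by several tests.
build_test_store <- function(n_patients = 6L, seed = 11L, salt = "unit-salt",
                             root = tempfile("dcm")) {
  world <- generate_world(fixture_config(n_patients = n_patients, seed = seed,
                                         cancer_rate = 0.3))
  emit_dicom_tree(world, root)
  store <- doc_store()
  report <- ingest_images(store, scan_dicom_tree(root), "unit")
  builds <- build_hierarchy(store, "unit")
  list(world = world, store = store, report = report, builds = builds,
       root = root, salt = salt)
}
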