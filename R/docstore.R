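#' An in-process document store
#'
#' Creates an empty store of named collections of documents.  A document is a
#' named list `body` plus store-assigned `id` and `metadata` (data-model
#' version, creation/modification timestamps, project name).  The store is the
#' one persistence contract shared by every ingestion module; the reference
#' backend is an in-process environment so no database server is needed, and
#' any collection can be round-tripped through newline-delimited JSON
#' ([ds_export_ndjson()]) for inspection or transport.
#'
#' Three conventions are enforced on stored bodies:
#' * missing values are represented by field *absence* — `NULL` fields are
#'   stripped recursively at insert/update time, never stored as placeholders;
#' * field names are `snake_case`;
#' * frequently accessed fields live at the body root, with rarely used
#'   detail (such as the full DICOM tag mapping) nested below it.
#'
#' @return An object of class `doc_store`.
#' @examples
#' store <- doc_store()
#' ds_register(store, "ImageMetadata")
#' id <- ds_insert(store, "ImageMetadata", list(file_path = "/a/b.dcm"), "pilot")
#' ds_get(store, "ImageMetadata", id)$body$file_path
#' @export
doc_store <- function() {
  store <- new.env(parent = emptyenv())
  store$collections <- new.env(parent = emptyenv())
  class(store) <- "doc_store"
  store
}

#' @export
print.doc_store <- function(x, ...) {
  nms <- ds_collections(x)
  cat("<doc_store> ", length(nms), " collection(s)\n", sep = "")
  for (nm in nms) cat("  ", nm, ": ", ds_count(x, nm), " document(s)\n", sep = "")
  invisible(x)
}

#' Register a collection (entity type) in a store
#'
#' Every entity type must be registered before documents can be inserted into
#' it; inserting into an unknown collection is an error, which catches typos
#' early.  Registration is idempotent.
#'
#' @param store A [doc_store()].
#' @param name Collection name (conventionally the entity type, e.g.
#'   `"ImageMetadata"`).
#' @return The store, invisibly.
#' @export
ds_register <- function(store, name) {
  stopifnot(inherits(store, "doc_store"), is.character(name), nzchar(name))
  for (nm in name) {
    if (is.null(store$collections[[nm]])) {
      coll <- new.env(parent = emptyenv())
      coll$docs <- list()
      coll$n <- 0L
      store$collections[[nm]] <- coll
    }
  }
  invisible(store)
}

ds_coll <- function(store, collection) {
  coll <- store$collections[[collection]]
  if (is.null(coll)) {
    abort(sprintf("collection '%s' is not registered", collection),
          class = "mammodb_registration_error")
  }
  coll
}

#' @rdname ds_register
#' @export
ds_collections <- function(store) {
  sort(ls(store$collections))
}

# Recursively drop NULL and length-zero fields so missingness is encoded as
# absence ("sparse is better than dense").
drop_missing_fields <- function(x) {
  if (!is.list(x)) return(x)
  x <- compact(x)
  x <- map(x, function(v) if (is.list(v)) drop_missing_fields(v) else v)
  x[map_int(x, length) > 0L | map_lgl(x, is.list)]
}

#' Insert a document
#'
#' Stamps metadata (`model_version`, `created_at`, `project_name`) and assigns
#' an id unique within the collection.  `NULL`-valued fields are stripped
#' rather than stored.
#'
#' @inheritParams ds_register
#' @param collection Registered collection name.
#' @param body Named list of fields (nesting allowed).
#' @param project Non-empty project name recorded in the metadata; lets
#'   several ethically distinct projects share one store and be filtered
#'   apart.
#' @return The assigned document id (a string).
#' @export
ds_insert <- function(store, collection, body, project) {
  coll <- ds_coll(store, collection)
  stopifnot(is.list(body))
  if (!is.character(project) || length(project) != 1L || !nzchar(project)) {
    abort("project must be a non-empty string")
  }
  coll$n <- coll$n + 1L
  id <- sprintf("%s-%06d", collection, coll$n)
  doc <- list(
    id = id,
    metadata = list(
      model_version = MODEL_VERSION,
      created_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS6%z"),
      project_name = project
    ),
    body = drop_missing_fields(body)
  )
  coll$docs[[id]] <- doc
  id
}

#' Fetch, update or enumerate documents
#'
#' `ds_update()` merges `patch` into the body (a `NULL` patch value deletes
#' the field) and stamps `modified_at`; `created_at` and `model_version` are
#' never rewritten.
#'
#' @inheritParams ds_insert
#' @param id Document id as returned by [ds_insert()].
#' @param patch Named list of body fields to set (or `NULL` to remove).
#' @return `ds_get()` the document (or `NULL`); `ds_ids()` a character vector;
#'   `ds_count()` an integer; `ds_docs()` a named list of documents.
#' @export
ds_get <- function(store, collection, id) {
  ds_coll(store, collection)$docs[[id]]
}

#' @rdname ds_get
#' @export
ds_update <- function(store, collection, id, patch) {
  coll <- ds_coll(store, collection)
  doc <- coll$docs[[id]]
  if (is.null(doc)) abort(sprintf("no document '%s' in '%s'", id, collection))
  stopifnot(is.list(patch), !is.null(names(patch)))
  for (nm in names(patch)) doc$body[[nm]] <- patch[[nm]]
  doc$body <- drop_missing_fields(doc$body)
  doc$metadata$modified_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%OS6%z")
  coll$docs[[id]] <- doc
  invisible(id)
}

#' @rdname ds_get
#' @param project Optional project filter.
#' @export
ds_ids <- function(store, collection, project = NULL) {
  docs <- ds_coll(store, collection)$docs
  ids <- names(docs)
  if (!is.null(project)) {
    ids <- ids[map_chr(docs, function(d) d$metadata$project_name) == project]
  }
  ids
}

#' @rdname ds_get
#' @export
ds_count <- function(store, collection, project = NULL) {
  length(ds_ids(store, collection, project))
}

#' @rdname ds_get
#' @export
ds_docs <- function(store, collection, project = NULL) {
  ds_coll(store, collection)$docs[ds_ids(store, collection, project)]
}

#' @rdname ds_get
#' @param predicate Function of a document returning `TRUE` to keep it.
#' @export
ds_find <- function(store, collection, predicate, project = NULL) {
  keep(ds_docs(store, collection, project), predicate)
}

# Follow a dotted path ("dicom_tags.SeriesInstanceUID.value") into a body.
get_path <- function(body, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  for (p in parts) {
    if (!is.list(body) || is.null(body[[p]])) return(NULL)
    body <- body[[p]]
  }
  body
}

# Sentinel label for documents lacking a grouping key.  Real values are
# serialized, so the sentinel cannot collide with them.
MISSING_KEY <- "<missing>"

key_label <- function(value) {
  if (is.null(value)) return(MISSING_KEY)
  paste(as.character(unlist(value)), collapse = "\\")
}

#' Group documents by one or more body field paths
#'
#' The document-store analogue of an aggregation-pipeline `$group`: every
#' document of the collection is assigned to exactly one group keyed by the
#' tuple of values found at `key_paths` (dotted paths into the body).
#' Documents lacking a key path are collected under the explicit sentinel
#' `"<missing>"` rather than silently dropped or merged, so callers decide
#' what to do with them.
#'
#' @inheritParams ds_insert
#' @param key_paths Non-empty character vector of dotted field paths.
#' @param project Optional project filter.
#' @return A tibble with one row per group: one character column per key path
#'   and a list-column `ids` of member document ids.
#' @export
ds_group_by <- function(store, collection, key_paths, project = NULL) {
  if (length(key_paths) == 0L) abort("key_paths must be non-empty")
  docs <- ds_docs(store, collection, project)
  if (length(docs) == 0L) {
    out <- c(as.list(stats::setNames(rep(list(character()), length(key_paths)), key_paths)),
             list(ids = list()))
    return(as_tibble(out))
  }
  keys <- map(docs, function(d) map_chr(key_paths, function(p) key_label(get_path(d$body, p))))
  tab <- tibble(
    .key = map_chr(keys, paste, collapse = "\x1f"),
    .id = names(docs)
  )
  grouped <- tab |>
    group_by(.data$.key) |>
    summarise(ids = list(.data$.id), .groups = "drop")
  parts <- do.call(rbind, strsplit(grouped$.key, "\x1f", fixed = TRUE))
  out <- as_tibble(stats::setNames(as.data.frame(parts, stringsAsFactors = FALSE), key_paths))
  out$ids <- grouped$ids
  out
}

#' Export or import a collection as newline-delimited JSON
#'
#' One JSON object per line (`id`, `metadata`, `body`); the inverse of each
#' other, so collections can be inspected, version-controlled or shipped as
#' plain text.
#'
#' @inheritParams ds_insert
#' @param path File path.
#' @return `ds_export_ndjson()` the number of documents written;
#'   `ds_import_ndjson()` the number read.
#' @export
ds_export_ndjson <- function(store, collection, path) {
  docs <- ds_docs(store, collection)
  lines <- map_chr(docs, function(d) {
    jsonlite::toJSON(d, auto_unbox = TRUE, null = "null", digits = NA)
  })
  writeLines(lines, path, useBytes = TRUE)
  length(lines)
}

#' @rdname ds_export_ndjson
#' @export
ds_import_ndjson <- function(store, collection, path) {
  ds_register(store, collection)
  coll <- ds_coll(store, collection)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  for (ln in lines) {
    doc <- jsonlite::fromJSON(ln, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE)
    coll$docs[[doc$id]] <- doc
    idx <- suppressWarnings(as.integer(sub("^.*-", "", doc$id)))
    if (!is.na(idx) && idx > coll$n) coll$n <- idx
  }
  length(lines)
}
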