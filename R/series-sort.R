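# Study-directory restructuring: purge invalid files, sort into one
# subfolder per series, delete by metadata predicate.

.SERIES_INDEX_FILE <- "series_index.json"

.listStudyFiles <- function(studyDir, recursive = FALSE) {
  files <- list.files(studyDir, full.names = TRUE, recursive = recursive,
                      all.files = FALSE)
  files <- files[!dir.exists(files)]
  files[basename(files) != .SERIES_INDEX_FILE]
}

#' Purge non-DICOM and corrupted files from a study directory
#'
#' Classifies every file directly inside `studyDir` (see [classifyFile()])
#' and reports the non-valid ones. With `delete = TRUE` the reported files
#' are removed; valid files are never touched.
#'
#' @param studyDir study directory.
#' @param delete remove the non-valid files (default `FALSE`: report only).
#' @return data frame with columns `path`, `status`, `detail`, one row per
#'   non-valid file (zero rows when the directory is clean).
#' @export
purgeInvalid <- function(studyDir, delete = FALSE) {
  if (!dir.exists(studyDir))
    stop("purgeInvalid: not a readable directory: ", studyDir)
  files <- .listStudyFiles(studyDir)
  rows <- lapply(files, function(f) {
    cls <- classifyFile(f)
    if (cls@status == "valid") NULL else
      data.frame(path = f, status = cls@status, detail = cls@detail)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(path = character(), status = character(),
                      detail = character())
  if (delete && nrow(out)) unlink(out$path)
  out
}

# Series key assignment: identity is the Series Instance UID; the subfolder
# NAME is the Series Number. Two UIDs sharing a number get "-2", "-3", ...
# suffixes (deterministic: UID order).
.assignSeriesKeys <- function(uids, numbers) {
  uniq <- sort(unique(uids))
  keys <- character(length(uniq)); names(keys) <- uniq
  used <- character()
  for (u in uniq) {
    num <- numbers[match(u, uids)]
    base <- if (is.na(num)) "NA" else as.character(num)
    key <- base; k <- 1L
    while (key %in% used) {
      k <- k + 1L
      key <- paste0(base, "-", k)
    }
    used <- c(used, key)
    keys[[u]] <- key
  }
  keys
}

#' Sort a study directory into per-series subfolders
#'
#' Moves every DICOM file in `studyDir` into one subfolder per series. The
#' series is identified by its Series Instance UID; the subfolder is named
#' by the Series Number (with a numeric suffix when two distinct UIDs share
#' a number — reported in the returned index). Within each series the index
#' lists files by ascending instance number, ties broken by filename.
#' Re-running on an already sorted tree is a no-op. A machine-readable copy
#' of the index is written to `series_index.json` inside the study.
#'
#' @param studyDir directory containing only valid DICOM files (run
#'   [purgeInvalid()] first), possibly already partially sorted.
#' @param copy copy files instead of moving them.
#' @return a [SeriesIndex-class] reflecting the final layout.
#' @export
sortStudy <- function(studyDir, copy = FALSE) {
  if (!dir.exists(studyDir)) stop("sortStudy: no such directory: ", studyDir)
  files <- .listStudyFiles(studyDir, recursive = TRUE)
  if (!length(files))
    return(new("SeriesIndex", index = list(), uids = character(),
               collisions = character()))
  slices <- lapply(files, readSlice)
  uids <- vapply(slices, function(s)
    if (nzchar(s@seriesUID)) s@seriesUID else
      paste0("number:", s@seriesNumber), "")
  numbers <- vapply(slices, function(s) s@seriesNumber, 1L)
  instances <- vapply(slices, function(s) s@instanceNumber, 1L)
  keys <- .assignSeriesKeys(uids, numbers)
  fileKeys <- keys[uids]

  dest <- file.path(studyDir, fileKeys, basename(files))
  for (i in seq_along(files)) {
    if (normalizePath(files[i]) == normalizePath(dest[i], mustWork = FALSE))
      next
    dir.create(dirname(dest[i]), showWarnings = FALSE)
    if (file.exists(dest[i]))
      stop("sortStudy: destination already exists: ", dest[i])
    ok <- if (copy) file.copy(files[i], dest[i]) else
      file.rename(files[i], dest[i])
    if (!ok) stop("sortStudy: could not place ", files[i])
  }
  # drop directories emptied by the move
  if (!copy) {
    dirs <- list.dirs(studyDir, recursive = TRUE)[-1L]
    for (d in rev(dirs))
      if (!length(list.files(d, all.files = TRUE, no.. = TRUE))) unlink(d,
        recursive = TRUE)
  }

  index <- list(); uidOut <- character()
  for (key in sort(unique(fileKeys))) {
    sel <- which(fileKeys == key)
    ord <- sel[order(instances[sel], basename(files[sel]))]
    index[[key]] <- dest[ord]
    uidOut[[key]] <- uids[sel[1L]]
  }
  collisions <- grep("-[0-9]+$", names(index), value = TRUE)
  out <- new("SeriesIndex", index = index, uids = uidOut,
             collisions = collisions)
  jsonlite::write_json(
    list(series = lapply(index, basename), uids = as.list(uidOut),
         collisions = collisions),
    file.path(studyDir, .SERIES_INDEX_FILE), auto_unbox = TRUE,
    pretty = TRUE)
  out
}

.PREDICATE_FIELDS <- list(
  slice_thickness = function(s) s@sliceThickness,
  series_number = function(s) s@seriesNumber,
  instance_number = function(s) s@instanceNumber,
  series_uid = function(s) s@seriesUID,
  rescale_slope = function(s) s@rescaleSlope,
  rescale_intercept = function(s) s@rescaleIntercept,
  pixel_spacing_row = function(s) s@pixelSpacing[1],
  pixel_spacing_col = function(s) s@pixelSpacing[2])

#' Delete DICOM files matching a metadata predicate
#'
#' Applies `attribute comparator value` to every DICOM file under
#' `studyDir` (recursively) and deletes the matches. Files on which the
#' attribute cannot be resolved are skipped and reported, never deleted.
#'
#' The attribute is either one of the named fields `slice_thickness`,
#' `series_number`, `instance_number`, `series_uid`, `rescale_slope`,
#' `rescale_intercept`, `pixel_spacing_row`, `pixel_spacing_col`, or a
#' `GGGGEEEE` hexadecimal tag key resolved through the slice metadata.
#'
#' @param studyDir study directory.
#' @param attribute attribute name (see above).
#' @param comparator one of `"=="`, `"!="`, `">"`, `">="`, `"<"`, `"<="`.
#' @param value value to compare against (numeric or string).
#' @return list with `deleted` (paths removed) and `skipped` (paths where
#'   the attribute was unresolvable).
#' @export
deleteByMetadata <- function(studyDir, attribute, comparator, value) {
  if (!dir.exists(studyDir))
    stop("deleteByMetadata: no such directory: ", studyDir)
  cmp <- switch(comparator,
    "==" = `==`, "!=" = `!=`, ">" = `>`, ">=" = `>=`, "<" = `<`,
    "<=" = `<=`,
    stop("deleteByMetadata: malformed predicate: unknown comparator '",
         comparator, "'"))
  if (!is.character(attribute) || length(attribute) != 1L ||
      !nzchar(attribute))
    stop("deleteByMetadata: malformed predicate: bad attribute name")
  files <- .listStudyFiles(studyDir, recursive = TRUE)
  files <- files[vapply(files, function(f)
    classifyFile(f)@status == "valid", TRUE)]
  deleted <- character(); skipped <- character()
  for (f in files) {
    s <- readSlice(f)
    v <- if (!is.null(.PREDICATE_FIELDS[[attribute]]))
      .PREDICATE_FIELDS[[attribute]](s)
    else extraTags(s)[[toupper(attribute)]]
    if (is.null(v) || length(v) == 0L || (length(v) == 1L && is.na(v))) {
      skipped <- c(skipped, f)
      next
    }
    hit <- tryCatch(isTRUE(any(cmp(v, value))), error = function(e) NA)
    if (is.na(hit)) {
      skipped <- c(skipped, f)
    } else if (hit) {
      unlink(f)
      deleted <- c(deleted, f)
    }
  }
  list(deleted = deleted, skipped = skipped)
}
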