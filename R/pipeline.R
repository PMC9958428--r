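# Pipeline orchestration: configuration, staged execution, run manifest.

#' Run manifest
#'
#' Record of one [runPipeline()] invocation: every input file with its
#' classification and the actions taken, every output produced with its
#' format class (`image`, `volume`, `mesh`), per-stage counts, the full
#' configuration snapshot, and timestamps.
#'
#' @slot files data frame: `path`, `study`, `classification`, `action`,
#'   `series`.
#' @slot outputs data frame: `path`, `study`, `series`, `class`, `source`.
#' @slot counts named list of per-stage counts.
#' @slot config the configuration list used.
#' @slot timestamps character: `started`, `finished`.
#' @exportClass RunManifest
setClass("RunManifest",
  representation(files = "data.frame", outputs = "data.frame",
                 counts = "list", config = "list",
                 timestamps = "character"),
  validity = function(object) {
    if (anyDuplicated(object@files$path))
      return("every input file must appear exactly once")
    TRUE
  })

#' @describeIn runPipeline distinct output format classes in a manifest.
#' @param manifest a [RunManifest-class].
#' @export
outputClasses <- function(manifest) {
  stopifnot(is(manifest, "RunManifest"))
  sort(unique(manifest@outputs$class))
}

setMethod("show", "RunManifest", function(object) {
  cat("RunManifest:", length(unique(object@files$study)), "studies,",
      nrow(object@files), "input files,", nrow(object@outputs),
      "outputs\n")
  for (nm in names(object@counts))
    cat(sprintf("  %s: %s\n", nm, object@counts[[nm]]))
})

.CONFIG_DEFAULTS <- list(
  input_root = NA_character_,
  stages = c("sort", "denoise", "images", "nifti", "stl"),
  tissue_lower = -300, tissue_upper = 3000,
  bone_lower = 200, bone_upper = 3000,
  window_min = 200, window_max = 3000,
  image_format = "png", jpeg_quality = 95, binary_threshold = FALSE,
  out_root = NA_character_,
  copy_first = FALSE, raw_mode = FALSE,
  mask_mode = "slice", close_radius = 3,
  delete_invalid = TRUE, compress_nifti = FALSE,
  stl_ascii = FALSE, stl_decimate = 1,
  log_level = "info")

.validateConfig <- function(cfg) {
  unknown <- setdiff(names(cfg), names(.CONFIG_DEFAULTS))
  if (length(unknown))
    stop("config: unknown key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(.CONFIG_DEFAULTS, cfg)
  if (is.character(cfg$stages) && length(cfg$stages) == 1L)
    cfg$stages <- strsplit(cfg$stages, "[,; ]+")[[1]]
  bad <- setdiff(cfg$stages, c("sort", "denoise", "images", "nifti", "stl"))
  if (length(bad)) stop("config: unknown stage(s): ",
                        paste(bad, collapse = ", "))
  if (!length(cfg$stages)) stop("config: at least one stage must be enabled")
  needsDenoise <- intersect(cfg$stages, c("images", "nifti", "stl"))
  if ("denoise" %in% cfg$stages && !"sort" %in% cfg$stages)
    stop("config: stage 'denoise' requires stage 'sort'")
  if (length(needsDenoise) && !isTRUE(cfg$raw_mode) &&
      !"denoise" %in% cfg$stages)
    stop("config: stage(s) ", paste(needsDenoise, collapse = ", "),
         " require 'denoise' (or set raw_mode: true)")
  if (cfg$tissue_lower >= cfg$tissue_upper ||
      cfg$bone_lower >= cfg$bone_upper)
    stop("config: threshold bands need lower < upper")
  if (cfg$window_min >= cfg$window_max)
    stop("config: window_min must be < window_max")
  if (!cfg$image_format %in% c("png", "jpeg"))
    stop("config: image_format must be png or jpeg")
  if (!cfg$mask_mode %in% c("slice", "volume"))
    stop("config: mask_mode must be slice or volume")
  if (!cfg$log_level %in% c("debug", "info", "quiet"))
    stop("config: log_level must be debug, info or quiet")
  cfg
}

#' Load and validate a pipeline configuration
#'
#' Reads a flat YAML key/value file, fills defaults, and validates:
#' unknown keys are an error (typo protection), threshold/window bands
#' must be ordered, and enabled stages must respect the pipeline order —
#' `denoise` requires `sort`, and the export stages require `denoise`
#' unless `raw_mode` is set. An empty file yields the full default
#' configuration.
#'
#' @param path YAML file; `NULL` for pure defaults.
#' @return validated configuration list.
#' @export
loadConfig <- function(path = NULL) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("loadConfig: no such file: ", path)
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) cfg <- list()
  }
  .validateConfig(cfg)
}

.logMsg <- function(cfg, level, ...) {
  levels <- c(debug = 1L, info = 2L, quiet = 3L)
  if (levels[[cfg$log_level]] <= levels[[level]])
    message("[", level, "] ", ...)
}

.studyDirs <- function(root) {
  subs <- list.dirs(root, recursive = FALSE)
  subs <- subs[!startsWith(basename(subs), "_")]
  if (length(subs)) subs else root
}

#' Run the CT pre-processing pipeline
#'
#' Executes the enabled stages in order over every study directory under
#' `input_root`: series sorting (with purge of invalid files), in-place
#' couch/noise removal, and the three export classes — 2-D images, one
#' NIfTI volume per series, one STL mesh per series. A failure inside one
#' study is recorded and does not abort the remaining studies. The
#' manifest is returned and also written as `run_manifest.json` beside the
#' outputs.
#'
#' DICOM files are modified in place by the denoise stage; set
#' `copy_first: true` to work on a copy under the output root instead.
#'
#' @param config configuration list from [loadConfig()], or a path to a
#'   YAML file, or `NULL` for defaults; `input_root` must be set (second
#'   argument overrides).
#' @param inputRoot convenience override of `config$input_root`.
#' @return a [RunManifest-class].
#' @export
runPipeline <- function(config = NULL, inputRoot = NULL) {
  cfg <- if (is.character(config)) loadConfig(config) else
    .validateConfig(if (is.null(config)) list() else config)
  if (!is.null(inputRoot)) cfg$input_root <- inputRoot
  if (is.na(cfg$input_root) || !dir.exists(cfg$input_root))
    stop("runPipeline: input_root does not exist: ", cfg$input_root)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  outRoot <- if (is.na(cfg$out_root))
    file.path(cfg$input_root, "_outputs") else cfg$out_root
  dir.create(outRoot, recursive = TRUE, showWarnings = FALSE)

  studies <- .studyDirs(cfg$input_root)
  if (isTRUE(cfg$copy_first)) {
    work <- file.path(outRoot, "_work")
    dir.create(work, recursive = TRUE, showWarnings = FALSE)
    copied <- character()
    for (s in studies) {
      dest <- file.path(work, basename(s))
      dir.create(dest, showWarnings = FALSE)
      file.copy(.listStudyFiles(s, recursive = TRUE), dest)
      copied <- c(copied, dest)
    }
    studies <- copied
  }

  tspec <- thresholdSpec(cfg$tissue_lower, cfg$tissue_upper,
                         cfg$bone_lower, cfg$bone_upper)
  wspec <- windowSpec(cfg$window_min, cfg$window_max, cfg$image_format,
                      cfg$jpeg_quality, isTRUE(cfg$binary_threshold))

  fileRows <- list(); outRows <- list(); failures <- character()
  addOut <- function(path, study, series, class, source)
    outRows[[length(outRows) + 1L]] <<-
      data.frame(path = path, study = study, series = series,
                 class = class, source = source)

  for (study in studies) {
    studyName <- basename(study)
    res <- tryCatch({
      inputFiles <- .listStudyFiles(study, recursive = TRUE)
      cls <- vapply(inputFiles, function(f) classifyFile(f)@status, "")
      action <- ifelse(cls == "valid", "kept", "flagged")

      seriesDirs <- character()
      if ("sort" %in% cfg$stages) {
        bad <- purgeInvalid(study, delete = isTRUE(cfg$delete_invalid))
        if (isTRUE(cfg$delete_invalid) && nrow(bad))
          action[match(bad$path, inputFiles)] <- "deleted"
        idx <- sortStudy(study)
        .logMsg(cfg, "info", studyName, ": sorted ",
                sum(lengths(idx@index)), " files into ",
                length(idx@index), " series")
        seriesDirs <- file.path(study, names(idx@index))
        action[cls == "valid"] <- "sorted"
      } else {
        seriesDirs <- list.dirs(study, recursive = FALSE)
        if (!length(seriesDirs)) seriesDirs <- study
      }

      if ("denoise" %in% cfg$stages) {
        for (sd in seriesDirs) {
          rep <- denoiseSeries(sd, tspec, mode = cfg$mask_mode,
                               closeRadius = cfg$close_radius)
          .logMsg(cfg, "info", studyName, "/", basename(sd),
                  ": denoised ", sum(rep$status == "denoised"), " slices")
          action[cls == "valid"] <- "denoised"
        }
      }

      for (sd in seriesDirs) {
        key <- basename(sd)
        if ("images" %in% cfg$stages) {
          outDir <- file.path(outRoot, "images", studyName, key)
          written <- exportSeriesImages(sd, wspec, outDir)
          for (w in written) addOut(w, studyName, key, "image", sd)
        }
        if ("nifti" %in% cfg$stages) {
          vol <- stackSeries(sd)
          out <- file.path(outRoot, "nifti",
                           paste0(studyName, "_series", key, ".nii"))
          writeVolumeNifti(vol, out, compress = isTRUE(cfg$compress_nifti))
          addOut(out, studyName, key, "volume", sd)
        }
        if ("stl" %in% cfg$stages) {
          out <- file.path(outRoot, "stl",
                           paste0(studyName, "_series", key, ".stl"))
          seriesToSTL(sd, tspec, out,
                      mode = if (isTRUE(cfg$stl_ascii)) "ascii" else
                        "binary",
                      decimate = cfg$stl_decimate)
          addOut(out, studyName, key, "mesh", sd)
        }
      }
      data.frame(path = inputFiles, study = studyName,
                 classification = cls, action = action,
                 series = NA_character_)
    }, error = function(e) {
      .logMsg(cfg, "info", studyName, ": FAILED: ", conditionMessage(e))
      failures <<- c(failures, studyName)
      data.frame(path = character(), study = character(),
                 classification = character(), action = character(),
                 series = character())
    })
    fileRows[[study]] <- res
  }

  files <- do.call(rbind, c(fileRows, list(make.row.names = FALSE)))
  outputs <- if (length(outRows))
    do.call(rbind, c(outRows, list(make.row.names = FALSE)))
  else data.frame(path = character(), study = character(),
                  series = character(), class = character(),
                  source = character())
  counts <- list(
    studies = length(studies), failures = length(failures),
    files_in = nrow(files),
    valid = sum(files$classification == "valid"),
    invalid = sum(files$classification != "valid"),
    images = sum(outputs$class == "image"),
    volumes = sum(outputs$class == "volume"),
    meshes = sum(outputs$class == "mesh"))
  manifest <- new("RunManifest", files = files, outputs = outputs,
                  counts = counts, config = cfg,
                  timestamps = c(started = started,
                                 finished = format(Sys.time(),
                                                   "%Y-%m-%dT%H:%M:%S%z")))
  jsonlite::write_json(
    list(files = files, outputs = outputs, counts = counts,
         config = cfg,
         timestamps = as.list(manifest@timestamps),
         failures = failures),
    file.path(outRoot, "run_manifest.json"), auto_unbox = TRUE,
    pretty = TRUE, na = "null")
  manifest
}
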