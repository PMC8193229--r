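## Readers/writers for frame stacks, detection/annotation tables and feature
## tables. Frame indices are 0-based; boxes are 0-based half-open
## [x_min, x_max) x [y_min, y_max) pixel rectangles.

DETECTION_COLUMNS <- c("case_id", "frame", "label", "x_min", "y_min",
                       "x_max", "y_max", "score")

empty_detection_table <- function() {
  data.frame(case_id = character(0), frame = integer(0),
             label = character(0), x_min = integer(0), y_min = integer(0),
             x_max = integer(0), y_max = integer(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Construct a DSA frame stack
#'
#' @param frames List of 2D numeric/integer matrices (grayscale frames), all
#'   with identical dimensions; frame index is 0-based.
#' @param case_id Case identifier.
#' @param frame_interval_ms Frame interval in milliseconds.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, case_id = "case", frame_interval_ms = 250) {
  if (!is.list(frames) || length(frames) < 1L) {
    stop_("a frame stack needs at least one frame")
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_("all frames must have identical dimensions")
  }
  structure(list(case_id = case_id, frames = frames,
                 frame_interval_ms = frame_interval_ms),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("DSA frame stack '%s': %d frames of %dx%d px @ %.1f ms/frame\n",
              x$case_id, length(x$frames), d[2], d[1], x$frame_interval_ms))
  invisible(x)
}

#' @export
length.frame_stack <- function(x) length(x$frames)

## Read one grayscale image file to an integer matrix on the 0..255 scale
## (multi-channel images are reduced to their first channel).
read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
    stop_("unsupported frame format: %s", path))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  if (max(img) <= 1) img <- img * 255
  matrix(as.integer(round(img)), nrow = nrow(img))
}

#' Read a DSA frame stack
#'
#' Accepts either a directory of numbered PNG/TIFF frames or a single
#' multipage TIFF. Directory frames are ordered by the trailing integer in
#' the file name (numeric-aware, so `frame_2` sorts before `frame_10`);
#' files without a trailing integer fall back to lexicographic order.
#'
#' @param path Directory of frames or a multipage TIFF file.
#' @param frame_interval_ms Frame interval in milliseconds.
#' @param case_id Case identifier; defaults to the base name of `path`.
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(path, frame_interval_ms = 250, case_id = NULL) {
  case_id <- case_id %||% sub("\\.[^.]*$", "", basename(path))
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0L) stop_("no frames found in %s", path)
    num <- suppressWarnings(
      as.integer(sub(".*?([0-9]+)\\.[^.]*$", "\\1", basename(files))))
    ord <- if (anyNA(num)) order(basename(files)) else order(num)
    frames <- lapply(files[ord], read_gray)
  } else if (file.exists(path)) {
    if (!tolower(tools::file_ext(path)) %in% c("tif", "tiff")) {
      stop_("single-file stacks must be multipage TIFF: %s", path)
    }
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    frames <- lapply(pages, function(img) {
      if (length(dim(img)) == 3L) img <- img[, , 1L]
      if (max(img) <= 1) img <- img * 255
      matrix(as.integer(round(img)), nrow = nrow(img))
    })
  } else {
    stop_("path does not exist: %s", path)
  }
  frame_stack(frames, case_id = case_id,
              frame_interval_ms = frame_interval_ms)
}

validate_detection_table <- function(df) {
  missing <- setdiff(DETECTION_COLUMNS, names(df))
  if (length(missing)) {
    stop_("detection table is missing column(s): %s",
          paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) return(invisible(df))
  bad <- which(!(df$label %in% DSA_CLASSES))
  if (length(bad)) {
    stop_("unknown structure label \"%s\" in detection table row %d",
          df$label[bad[1]], bad[1])
  }
  bad <- which(df$x_min >= df$x_max | df$y_min >= df$y_max)
  if (length(bad)) {
    stop_("degenerate box (empty area) in detection table row %d", bad[1])
  }
  if (any(df$frame < 0)) stop_("frame indices must be >= 0 (0-based)")
  sc <- df$score[!is.na(df$score)]
  if (length(sc) && (any(sc < 0) || any(sc > 1))) {
    stop_("scores must lie in [0, 1]")
  }
  invisible(df)
}

#' Write / read a detection or annotation table
#'
#' CSV with the fixed header
#' `case_id,frame,label,x_min,y_min,x_max,y_max,score`. Ground-truth rows
#' leave `score` empty and are read back with `score = NA`. Write followed
#' by read is an identity.
#'
#' @param rows Data frame with the detection-table columns; `frame` 0-based,
#'   boxes half-open, `label` one of [dsa_classes()].
#' @param path CSV path.
#' @return `read_detection_table()` returns the validated data frame.
#' @export
write_detection_table <- function(rows, path) {
  validate_detection_table(rows)
  utils::write.csv(rows[, DETECTION_COLUMNS], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_detection_table
#' @export
read_detection_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(case_id = "character",
                                       label = "character"))
  df$score <- as.numeric(df$score)
  validate_detection_table(df)
  df
}

#' Write a per-case feature table
#'
#' One row per case: `case_id`, `diagnosis`, `grade_class`, the five
#' temporal features `T1..T5`, then the radiomic features in their
#' canonical frame-major order. All cases must share an identical feature
#' name set; writing is deterministic (identical input gives a
#' byte-identical file).
#'
#' @param cases List of per-case lists with elements `case_id`, `diagnosis`,
#'   `grade_class`, `temporal` (named, length 5) and `radiomics` (named).
#' @param path CSV path.
#' @export
write_feature_table <- function(cases, path) {
  if (length(cases) == 0L) {
    utils::write.csv(data.frame(case_id = character(0),
                                diagnosis = character(0),
                                grade_class = character(0)),
                     path, row.names = FALSE)
    return(invisible(path))
  }
  feat_names <- c(names(cases[[1]]$temporal), names(cases[[1]]$radiomics))
  rows <- lapply(cases, function(cs) {
    nm <- c(names(cs$temporal), names(cs$radiomics))
    if (!identical(nm, feat_names)) {
      stop_("case %s has a different feature set", cs$case_id)
    }
    c(list(case_id = cs$case_id, diagnosis = cs$diagnosis,
           grade_class = cs$grade_class),
      as.list(c(cs$temporal, cs$radiomics)))
  })
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return Data frame with metadata columns followed by feature columns.
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
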