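#' @name io
#' @title Readers and writers for the package's file dialects
#'
#' @description
#' All formats are plain text. Sensor CSV: header `timestamp_ms,x,y,z`, one
#' row per sample. Detection CSV: `frame_index,timestamp_ms,class,confidence,
#' x_min,y_min,x_max,y_max`; a row with an empty class field marks a frame
#' without boxes so empty frames survive a round trip. Detection JSON: an
#' array of per-frame records with a `boxes` list of the same fields.
#' Annotation CSV: `start_ms,end_ms,class,subject,session`. Offsets CSV:
#' `source,offset_ms`. Catalog: one class name per line. Timestamps are
#' integer milliseconds throughout.
NULL

#' Read a wrist-sensor CSV file
#'
#' @param path CSV file with header `timestamp_ms,x,y,z`.
#' @param device_id,position,nominal_rate_hz Stream metadata (not stored in
#'   the CSV; typically from a sidecar config).
#' @return An [inertial_stream()]. Malformed rows, duplicate or retrograde
#'   timestamps abort with the offending line number.
#' @export
read_sensor_csv <- function(path, device_id = "unknown",
                            position = "left_wrist", nominal_rate_hz = 50) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp_ms", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop(path, ": expected header ", paste(need, collapse = ","))
  }
  if (nrow(df) == 0L) stop(path, ": empty sensor file")
  bad <- which(!stats::complete.cases(df[need]) |
                 !vapply(seq_len(nrow(df)),
                         function(i) all(is.finite(as.numeric(df[i, need]))),
                         logical(1)))
  if (length(bad) > 0L) {
    stop(path, ": malformed row at line ", bad[1L] + 1L)
  }
  dt <- diff(df$timestamp_ms)
  if (any(dt == 0)) {
    stop(path, ": duplicate timestamp at line ", which(dt == 0)[1L] + 2L)
  }
  if (any(dt < 0)) {
    stop(path, ": retrograde timestamp at line ", which(dt < 0)[1L] + 2L)
  }
  inertial_stream(df$timestamp_ms, df$x, df$y, df$z, device_id = device_id,
                  position = position, nominal_rate_hz = nominal_rate_hz)
}

#' Write a wrist-sensor CSV file
#' @param stream An [inertial_stream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensor_csv <- function(stream, path) {
  df <- stream$samples
  names(df)[1L] <- "timestamp_ms"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-frame object detections
#'
#' Both dialects yield identical [detection_track()] objects for equivalent
#' content. Boxes with inverted coordinates or confidences outside `[0, 1]`
#' are rejected row-wise with a warning; classes missing from `catalog` warn
#' but are kept.
#'
#' @param path Input file.
#' @param dialect `"csv"` or `"json"`.
#' @param catalog Optional class catalog used to warn on unknown classes.
#' @return A [detection_track()].
#' @export
read_detections <- function(path, dialect = c("csv", "json"),
                            catalog = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(class = "character"))
    need <- c("frame_index", "timestamp_ms", "class", "confidence",
              "x_min", "y_min", "x_max", "y_max")
    if (!all(need %in% names(df))) {
      stop(path, ": expected header ", paste(need, collapse = ","))
    }
    frames <- unique(df[c("frame_index", "timestamp_ms")])
    frames <- frames[order(frames$frame_index), ]
    names(frames) <- c("frame_index", "frame_t")
    rownames(frames) <- NULL
    boxes <- df[nzchar(df$class), , drop = FALSE]
  } else {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    frames <- data.frame(
      frame_index = vapply(recs, function(r) as.integer(r$frame_index),
                           integer(1)),
      frame_t = vapply(recs, function(r) as.numeric(r$timestamp_ms),
                       numeric(1)))
    boxes <- do.call(rbind, lapply(recs, function(r) {
      if (length(r$boxes) == 0L) return(NULL)
      do.call(rbind, lapply(r$boxes, function(b) {
        data.frame(frame_index = as.integer(r$frame_index),
                   class = as.character(b$class),
                   confidence = as.numeric(b$confidence),
                   x_min = as.numeric(b$x_min), y_min = as.numeric(b$y_min),
                   x_max = as.numeric(b$x_max), y_max = as.numeric(b$y_max))
      }))
    }))
    if (is.null(boxes)) {
      boxes <- data.frame(frame_index = integer(0), class = character(0),
                          confidence = numeric(0), x_min = numeric(0),
                          y_min = numeric(0), x_max = numeric(0),
                          y_max = numeric(0))
    }
  }
  boxes <- boxes[c("frame_index", "class", "confidence",
                   "x_min", "y_min", "x_max", "y_max")]
  bad_conf <- boxes$confidence < 0 | boxes$confidence > 1
  if (any(bad_conf)) {
    warning(path, ": ", sum(bad_conf),
            " box(es) with confidence outside [0, 1] rejected")
    boxes <- boxes[!bad_conf, , drop = FALSE]
  }
  bad_box <- boxes$x_max <= boxes$x_min | boxes$y_max <= boxes$y_min
  if (any(bad_box)) {
    warning(path, ": ", sum(bad_box), " box(es) with inverted coordinates ",
            "rejected")
    boxes <- boxes[!bad_box, , drop = FALSE]
  }
  if (!is.null(catalog)) {
    unknown <- setdiff(unique(boxes$class), catalog)
    if (length(unknown) > 0L) {
      warning(path, ": classes outside catalog kept: ",
              paste(unknown, collapse = ", "))
    }
  }
  rownames(boxes) <- NULL
  detection_track(frames, boxes)
}

#' Write per-frame object detections
#' @param track A [detection_track()].
#' @param path Output path.
#' @param dialect `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_detections <- function(track, path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    merged <- merge(track$frames, track$boxes, by = "frame_index",
                    all.x = TRUE, sort = TRUE)
    merged$class[is.na(merged$class)] <- ""
    names(merged)[names(merged) == "frame_t"] <- "timestamp_ms"
    merged <- merged[order(merged$frame_index),
                     c("frame_index", "timestamp_ms", "class", "confidence",
                       "x_min", "y_min", "x_max", "y_max")]
    utils::write.csv(merged, path, row.names = FALSE, quote = FALSE,
                     na = "")
  } else {
    split_idx <- split(seq_len(nrow(track$boxes)), track$boxes$frame_index)
    recs <- lapply(seq_len(nrow(track$frames)), function(i) {
      fi <- track$frames$frame_index[i]
      rows <- split_idx[[as.character(fi)]]
      bx <- lapply(rows, function(r) {
        b <- track$boxes[r, ]
        list(class = b$class, confidence = b$confidence, x_min = b$x_min,
             y_min = b$y_min, x_max = b$x_max, y_max = b$y_max)
      })
      list(frame_index = fi, timestamp_ms = track$frames$frame_t[i],
           boxes = bx)
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read an annotation CSV
#' @param path CSV with header `start_ms,end_ms,class,subject,session`.
#' @return An [annotation_track()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(session = "character"))
  need <- c("start_ms", "end_ms", "class", "subject", "session")
  if (!all(need %in% names(df))) {
    stop(path, ": expected header ", paste(need, collapse = ","))
  }
  annotation_track(df$start_ms, df$end_ms, df$class,
                   subject = df$subject[1L], session = df$session[1L])
}

#' Write an annotation CSV
#' @param track An [annotation_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(track, path) {
  df <- as.data.frame(track)
  df$subject <- attr(track, "subject")
  df$session <- attr(track, "session")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a per-source offsets CSV
#' @param path CSV with header `source,offset_ms`.
#' @param reference Reference source name (offset 0).
#' @return An [alignment_offsets()] table.
#' @export
read_offsets <- function(path, reference) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  alignment_offsets(df, reference)
}

#' @rdname read_offsets
#' @param offsets A data frame with `source`, `offset_ms`.
#' @export
write_offsets <- function(offsets, path) {
  utils::write.csv(as.data.frame(offsets)[c("source", "offset_ms")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ordered class catalog (one class per line)
#' @param path Text file.
#' @return Character vector.
#' @export
read_catalog <- function(path) {
  x <- readLines(path, warn = FALSE)
  x[nzchar(trimws(x))]
}

#' Write an evaluation report as CSV and JSON
#'
#' The CSV carries one row per class plus a `macro` row, columns
#' `class,precision,recall,f1`; the JSON mirrors the full report.
#'
#' @param report An `eval_report`.
#' @param path_prefix Output path without extension; `.csv` and `.json` are
#'   appended.
#' @return The two paths, invisibly.
#' @export
write_report <- function(report, path_prefix) {
  df <- rbind(report$per_class,
              data.frame(class = "macro",
                         precision = report$macro[["precision"]],
                         recall = report$macro[["recall"]],
                         f1 = report$macro[["f1"]]))
  csv <- paste0(path_prefix, ".csv")
  js <- paste0(path_prefix, ".json")
  utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(per_class = report$per_class,
                            macro = as.list(report$macro),
                            n = report$n, scheme = report$scheme),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}

#' Write a cohort to disk
#'
#' One directory per session (`subjectS_sessionK`) containing `left.csv`,
#' `right.csv`, `detections.csv`, `annotations.csv`, `offsets.csv`, plus a
#' top-level `manifest.yaml` with the generating configuration summary and
#' per-file MD5 hashes.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory.
#' @param force Overwrite an existing directory (default `FALSE`).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, force = FALSE) {
  if (dir.exists(dir) && !force) {
    stop("output directory exists (use force = TRUE): ", dir)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  config <- attr(cohort, "config")
  files <- character(0)
  for (sess in cohort) {
    sdir <- file.path(dir, paste0(sess$subject, "_session", sess$session))
    dir.create(sdir, showWarnings = FALSE)
    write_sensor_csv(sess$streams$left_wrist, file.path(sdir, "left.csv"))
    write_sensor_csv(sess$streams$right_wrist, file.path(sdir, "right.csv"))
    write_detections(sess$detections, file.path(sdir, "detections.csv"),
                     "csv")
    write_annotations(sess$annotations, file.path(sdir, "annotations.csv"))
    write_offsets(sess$true_offsets, file.path(sdir, "offsets.csv"))
    files <- c(files, list.files(sdir, full.names = TRUE))
  }
  writeLines(config$catalog, file.path(dir, "catalog.txt"))
  files <- c(files, file.path(dir, "catalog.txt"))
  manifest <- list(
    generator = list(seed = config$seed, subjects = config$subjects,
                     sessions_per_subject = config$sessions_per_subject,
                     classes = config$classes,
                     imu_rate_hz = config$imu_rate_hz, fps = config$fps,
                     accel_noise_sd = config$accel_noise_sd),
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    sub(paste0("^", dir, "/?"), "", files))))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A `cohort` (without the generating config; the catalog is
#'   attached).
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  sdirs <- list.dirs(dir, recursive = FALSE)
  sessions <- lapply(sdirs, function(sdir) {
    ann <- read_annotations(file.path(sdir, "annotations.csv"))
    offs <- utils::read.csv(file.path(sdir, "offsets.csv"),
                            stringsAsFactors = FALSE)
    list(streams = list(
           left_wrist = read_sensor_csv(file.path(sdir, "left.csv"),
                                        device_id = "watch_left_wrist",
                                        position = "left_wrist"),
           right_wrist = read_sensor_csv(file.path(sdir, "right.csv"),
                                         device_id = "watch_right_wrist",
                                         position = "right_wrist")),
         detections = read_detections(file.path(sdir, "detections.csv"),
                                      "csv"),
         annotations = ann, true_offsets = offs,
         subject = attr(ann, "subject"), session = attr(ann, "session"))
  })
  catalog_path <- file.path(dir, "catalog.txt")
  structure(sessions,
            catalog = if (file.exists(catalog_path))
              read_catalog(catalog_path) else NULL,
            class = "cohort")
}
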