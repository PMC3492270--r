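## CSV I/O for tracks and descriptor tables.
##
## Numbers are written with "%.17g" so a written-and-reread track is
## bit-identical to the original; output is locale-independent (C-style '.'
## decimal, comma separator, LF line endings).

fmt_cell <- function(v) {
  if (is.numeric(v)) {
    ifelse(is.na(v), "", sprintf("%.17g", v))
  } else {
    ifelse(is.na(v), "", as.character(v))
  }
}

write_csv_stable <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con, sep = "\n")
  if (nrow(df)) {
    cols <- lapply(df, fmt_cell)
    lines <- do.call(paste, c(cols, sep = ","))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Write a track to CSV (with metadata sidecar)
#'
#' Pixel tracks keep columns `frame`, `t_s`, `x_px`, `y_px`; ground tracks
#' `t_s`, `x_cm`, `y_cm`. Gap rows are written with empty position fields.
#' Track attributes (generator parameters, labels, gaps) go to a
#' `<path>.json` sidecar so a read-back reconstructs the object exactly.
#'
#' @param track a `pixel_track` or `ground_track` data.frame.
#' @param path output CSV path.
#' @param sidecar write the metadata sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, sidecar = TRUE) {
  write_csv_stable(as.data.frame(track), path)
  if (sidecar) {
    meta <- list(class = class(track))
    for (at in c("params", "burrow", "direction_label", "excursion_number",
                 "gaps")) {
      if (!is.null(attr(track, at))) meta[[at]] <- attr(track, at)
    }
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a track CSV
#'
#' Column names decide the flavour (`x_px`/`y_px` pixel, `x_cm`/`y_cm`
#' ground). Unknown extra columns are preserved. Rows with non-increasing
#' timestamps are rejected with their file line number.
#'
#' @param path CSV path (a `<path>.json` sidecar, if present, restores
#'   metadata attributes).
#' @return a `pixel_track` or `ground_track` data.frame.
#' @export
read_track <- function(path) {
  if (!file.exists(path)) stopf("track file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (all(c("x_px", "y_px") %in% names(df))) {
    kind <- "pixel_track"
  } else if (all(c("x_cm", "y_cm") %in% names(df))) {
    kind <- "ground_track"
  } else {
    stopf("%s: no recognised position columns (x_px/y_px or x_cm/y_cm)", path)
  }
  if (!"t_s" %in% names(df)) stopf("%s: missing t_s column", path)
  bad <- which(diff(df$t_s) <= 0)
  if (length(bad)) {
    stopf("%s: non-increasing timestamp at line %d", path, bad[1] + 2L)
  }
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    for (at in setdiff(names(meta), "class")) {
      val <- meta[[at]]
      if (at == "gaps" && is.matrix(val)) {
        val <- lapply(seq_len(nrow(val)), function(i) as.integer(val[i, ]))
      }
      attr(df, at) <- val
    }
    class(df) <- unlist(meta$class)
  } else {
    class(df) <- c(kind, "data.frame")
  }
  df
}

#' Write / read a frame stack
#'
#' A path ending in `.tif`/`.tiff` stores a multi-page 8-bit TIFF; otherwise
#' the path is treated as a directory of numbered 8-bit PNG frames
#' (`frame_000001.png`, ...). Either way a `timestamps.json` sidecar records
#' frame times. Intensities are quantised to the 8-bit grid on write, as in
#' the original recordings.
#'
#' @param stack a [frame_stack()].
#' @param path output file (TIFF) or directory (PNGs).
#' @rdname frame_io
#' @export
write_frames <- function(stack, path) {
  n <- dim(stack$frames)[3]
  imgs <- lapply(seq_len(n), function(k) stack$frames[, , k] / 255)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(imgs, path, bits.per.sample = 8)
    side <- paste0(path, ".json")
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_len(n)) {
      png::writePNG(imgs[[k]], file.path(path, sprintf("frame_%06d.png", k)))
    }
    side <- file.path(path, "timestamps.json")
  }
  jsonlite::write_json(list(timestamps = stack$timestamps), side,
                       digits = NA)
  invisible(path)
}

#' @param frame_rate fallback frame rate (Hz) when no timestamp sidecar
#'   exists.
#' @rdname frame_io
#' @export
read_frames <- function(path, frame_rate = 25) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!file.exists(path)) stopf("frame stack not found: %s", path)
    imgs <- tiff::readTIFF(path, all = TRUE)
    side <- paste0(path, ".json")
  } else {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stopf("no PNG frames found in %s", path)
    imgs <- lapply(files, png::readPNG)
    side <- file.path(path, "timestamps.json")
  }
  imgs <- lapply(imgs, function(im) {
    if (length(dim(im)) == 3) {           # RGB(A) -> luma grayscale
      im <- 0.299 * im[, , 1] + 0.587 * im[, , 2] + 0.114 * im[, , 3]
    }
    im * 255
  })
  arr <- array(unlist(imgs), c(dim(imgs[[1]]), length(imgs)))
  ts <- if (file.exists(side)) {
    unlist(jsonlite::read_json(side, simplifyVector = TRUE)$timestamps)
  } else {
    (seq_along(imgs) - 1) / frame_rate
  }
  frame_stack(arr, ts)
}

#' Write a per-excursion summary table
#'
#' CSV shaped like a descriptive-statistics excursion table: direction,
#' excursion number, path length, duration, mean speed per row.
#'
#' @param summaries a data.frame of rows from [excursion_summary()].
#' @param path output CSV path.
#' @export
write_summary_table <- function(summaries, path) {
  write_csv_stable(as.data.frame(summaries), path)
  invisible(path)
}
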