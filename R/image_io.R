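#' Pixel calibration for a microscope setup
#'
#' Carries the physical pixel size of the camera/objective combination and the
#' bit depth of the acquired rasters. Every length and area reported by the
#' package is converted to micrometres through this object; the calibration is
#' always user-supplied because it depends on the microscope setup.
#'
#' @param microns_per_pixel Physical size of one pixel in micrometres (> 0).
#' @param bit_depth Integer bit depth of the acquisition; 8 is the working
#'   depth of the pipeline (16-bit inputs are rescaled on load).
#' @return An object of class `pixel_calibration`.
#' @examples
#' cal <- pixel_calibration(0.34)
#' @export
pixel_calibration <- function(microns_per_pixel, bit_depth = 8L) {
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1L ||
      !is.finite(microns_per_pixel) || microns_per_pixel <= 0) {
    stop("microns_per_pixel must be a single positive number", call. = FALSE)
  }
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) {
    stop("bit_depth must be 8 or 16", call. = FALSE)
  }
  structure(
    list(microns_per_pixel = as.numeric(microns_per_pixel),
         bit_depth = bit_depth),
    class = "pixel_calibration"
  )
}

#' @export
print.pixel_calibration <- function(x, ...) {
  cat(sprintf("pixel_calibration: %.6g um/px, %d-bit\n",
              x$microns_per_pixel, x$bit_depth))
  invisible(x)
}

# Read a single-channel raster as an integer matrix on the 0..255 scale.
# 16-bit inputs are mapped linearly by v -> floor(v/257 + 0.5) (round half up)
# so that 65535 -> 255; this keeps fixed 8-bit thresholds meaningful.
# Multi-channel images are rejected unless to_gray = TRUE, in which case the
# Rec. 601 luminance 0.299 R + 0.587 G + 0.114 B is used.
read_gray_image <- function(path, to_gray = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("image file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    depth <- attr(img, "bits.per.sample")
    if (is.null(depth)) depth <- if (max(img) > 255L) 16L else 8L
  } else if (ext == "png") {
    img <- png::readPNG(path)
    img <- round(img * 255)
    depth <- 8L
  } else {
    stop(sprintf("unsupported image format '.%s' (use TIFF or PNG): %s",
                 ext, path), call. = FALSE)
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) {
      img <- img[, , 1L]
    } else if (to_gray) {
      w <- c(0.299, 0.587, 0.114)
      img <- w[1] * img[, , 1L] + w[2] * img[, , 2L] + w[3] * img[, , 3L]
      img <- round(img)
    } else {
      stop(sprintf(
        "multi-channel image (%d channels): %s; pass to_gray = TRUE to convert",
        dim(img)[3], path), call. = FALSE)
    }
  }
  if (!depth %in% c(8L, 16L)) {
    stop(sprintf("unsupported bit depth %s in %s (expected 8 or 16)",
                 depth, path), call. = FALSE)
  }
  if (depth == 16L) {
    warning(sprintf("16-bit image rescaled to 8-bit (linear /257): %s",
                    basename(path)), call. = FALSE)
    img <- floor(img / 257 + 0.5)
  }
  storage.mode(img) <- "integer"
  if (min(img) < 0L || max(img) > 255L) {
    stop(sprintf("intensities outside [0, 255] after load: %s", path),
         call. = FALSE)
  }
  img
}

#' Load one co-registered brightfield / POM micrograph pair
#'
#' Reads the two frames of one field of view: a brightfield micrograph (dark
#' fiber on bright background) and the polarized-light micrograph of the exact
#' same area (bright birefringent fiber on dark background), acquired
#' back-to-back so no registration is needed.
#'
#' @param brightfield_path,pom_path Paths to 8- or 16-bit grayscale TIFF (or
#'   PNG) files of identical dimensions. 16-bit inputs are linearly rescaled
#'   to 8-bit (divide by 257, round half up) with a warning.
#' @param calibration A [pixel_calibration()].
#' @param fiber_id,frame_index Identifiers carried into all downstream tables.
#' @param to_gray Convert RGB inputs to luminance instead of rejecting them.
#' @return An `image_pair` with integer matrices `brightfield` and `pom` on
#'   the 0..255 scale.
#' @export
load_image_pair <- function(brightfield_path, pom_path, calibration,
                            fiber_id = "fiber", frame_index = 0L,
                            to_gray = FALSE) {
  stopifnot(inherits(calibration, "pixel_calibration"))
  bf <- read_gray_image(brightfield_path, to_gray = to_gray)
  pom <- read_gray_image(pom_path, to_gray = to_gray)
  if (!identical(dim(bf), dim(pom))) {
    stop(sprintf(
      "shape mismatch: brightfield %dx%d vs POM %dx%d (%s / %s)",
      nrow(bf), ncol(bf), nrow(pom), ncol(pom),
      basename(brightfield_path), basename(pom_path)), call. = FALSE)
  }
  image_pair(fiber_id, frame_index, bf, pom, calibration)
}

#' Construct an image pair from in-memory matrices
#'
#' @param fiber_id Fiber identifier.
#' @param frame_index Non-negative frame index along the fiber.
#' @param brightfield,pom Integer matrices with values in 0..255 and equal
#'   dimensions (rows = image rows, columns = position along the fiber).
#' @param calibration A [pixel_calibration()].
#' @return An object of class `image_pair`.
#' @export
image_pair <- function(fiber_id, frame_index, brightfield, pom, calibration) {
  stopifnot(inherits(calibration, "pixel_calibration"))
  frame_index <- as.integer(frame_index)
  if (is.na(frame_index) || frame_index < 0L) {
    stop("frame_index must be a non-negative integer", call. = FALSE)
  }
  if (!is.matrix(brightfield) || !is.matrix(pom) ||
      !identical(dim(brightfield), dim(pom))) {
    stop("brightfield and pom must be matrices of identical dimensions",
         call. = FALSE)
  }
  for (nm in c("brightfield", "pom")) {
    m <- get(nm)
    if (min(m) < 0 || max(m) > 255) {
      stop(sprintf("%s intensities must lie in [0, 255]", nm), call. = FALSE)
    }
  }
  storage.mode(brightfield) <- "integer"
  storage.mode(pom) <- "integer"
  structure(
    list(fiber_id = as.character(fiber_id), frame_index = frame_index,
         brightfield = brightfield, pom = pom, calibration = calibration),
    class = "image_pair"
  )
}

#' Discover fiber image series in a directory
#'
#' Pairs brightfield and POM frames by filename. The default pattern matches
#' names like `fiberA_f0_bf.tif` / `fiberA_f0_pom.tif`: capture group 1 is the
#' fiber id, group 2 the frame index, group 3 the modality token.
#'
#' @param directory Directory containing the micrographs.
#' @param calibration A [pixel_calibration()] shared by the whole series.
#' @param pattern Perl regular expression with three capture groups
#'   (fiber id, frame index, modality token), anchored to the file name.
#' @param modality_tokens Named character vector mapping the two modalities to
#'   the tokens used in group 3; defaults to `c(bf = "bf", pom = "pom")`.
#' @param to_gray Passed to [load_image_pair()].
#' @param load Load the pixel data (default). With `load = FALSE` the series
#'   carry path records instead of decoded images, so callers can isolate
#'   decode failures per fiber (as [run_analyze()] does).
#' @return A list of `fiber_series` objects (one per fiber, frames sorted by
#'   index), each a list with `fiber_id` and `pairs`. Unmatched or duplicated
#'   frames are hard errors naming the offending files.
#' @export
discover_series <- function(directory, calibration,
                            pattern = "^(.+)_f(\\d+)_(bf|pom)\\.(?:tif|tiff|png)$",
                            modality_tokens = c(bf = "bf", pom = "pom"),
                            to_gray = FALSE, load = TRUE) {
  stopifnot(inherits(calibration, "pixel_calibration"))
  if (!dir.exists(directory)) {
    stop(sprintf("directory not found: %s", directory), call. = FALSE)
  }
  files <- sort(list.files(directory))
  m <- regmatches(files, regexec(pattern, files, perl = TRUE))
  hit <- lengths(m) >= 4L
  if (!any(hit)) {
    warning(sprintf("no micrographs matching the pairing pattern in %s",
                    directory), call. = FALSE)
    return(list())
  }
  tab <- do.call(rbind, lapply(which(hit), function(i) {
    g <- m[[i]]
    data.frame(file = files[i], fiber_id = g[2],
               frame_index = as.integer(g[3]), modality = g[4],
               stringsAsFactors = FALSE)
  }))
  tab$modality <- names(modality_tokens)[match(tab$modality, modality_tokens)]
  if (anyNA(tab$modality)) {
    stop("modality token in a filename does not match modality_tokens",
         call. = FALSE)
  }
  key <- paste(tab$fiber_id, tab$frame_index, tab$modality)
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop(sprintf("duplicate (fiber, frame, modality) entries: %s",
                 paste(dups, collapse = "; ")), call. = FALSE)
  }
  wide <- stats::reshape(tab, idvar = c("fiber_id", "frame_index"),
                         timevar = "modality", direction = "wide")
  names(wide) <- sub("^file\\.", "", names(wide))
  orphan <- is.na(wide$bf) | is.na(wide$pom)
  if (any(orphan)) {
    o <- wide[orphan, ]
    stop(sprintf(
      "unmatched frames (missing counterpart): %s",
      paste(sprintf("%s frame %d (%s missing)", o$fiber_id, o$frame_index,
                    ifelse(is.na(o$bf), "brightfield", "POM")),
            collapse = "; ")), call. = FALSE)
  }
  wide <- wide[order(wide$fiber_id, wide$frame_index), ]
  lapply(split(wide, wide$fiber_id), function(w) {
    pairs <- lapply(seq_len(nrow(w)), function(i) {
      if (load) {
        load_image_pair(file.path(directory, w$bf[i]),
                        file.path(directory, w$pom[i]),
                        calibration, fiber_id = w$fiber_id[i],
                        frame_index = w$frame_index[i], to_gray = to_gray)
      } else {
        list(brightfield_path = file.path(directory, w$bf[i]),
             pom_path = file.path(directory, w$pom[i]),
             fiber_id = w$fiber_id[i], frame_index = w$frame_index[i])
      }
    })
    structure(list(fiber_id = w$fiber_id[1], pairs = pairs),
              class = "fiber_series")
  })
}

#' Write a results table as CSV
#'
#' One row per frame (frame-level tables) or per fiber (summary tables);
#' missing statistics (e.g. bright-segment means when no pixel is bright) are
#' written as empty fields, never as 0.
#'
#' @param records A data frame of result rows sharing one schema.
#' @param path Output CSV path.
#' @return Invisibly, the normalized path written.
#' @export
write_results_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(normalizePath(path))
}

#' Write a JSON run manifest
#'
#' Records the configuration (thresholds, calibration, seed) and per-fiber
#' frame counts of an analysis run so that every output table can be traced
#' back to the exact settings that produced it.
#'
#' @param manifest A named list.
#' @param path Output JSON path.
#' @return Invisibly, the path written.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
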