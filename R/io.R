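# Reading/writing frames (PNG, TIFF, JPEG), directory manifests for stacks
# and series, and tabular outputs. Standard format handling goes through the
# png/tiff/jpeg/jsonlite packages.

.fileExt <- function(path) tolower(tools::file_ext(path))

#' Read an image file into a Frame
#'
#' Supports PNG (8-bit), TIFF (8/16-bit, native integer values) and JPEG.
#' PNG/JPEG values are scaled to the 8-bit range; TIFFs keep their native
#' bit depth. Alpha channels are dropped.
#'
#' @param path image file path
#' @param metadata optional metadata list to attach
#' @return a \linkS4class{Frame}
#' @export
readFrame <- function(path, metadata = list()) {
  if (!file.exists(path)) stop(sprintf("cannot read image: %s", path))
  ext <- .fileExt(path)
  if (ext == "png") {
    img <- png::readPNG(path)
    bd <- 8L
    px <- img * 255
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bits <- attr(img, "bits.per.sample")
    bd <- if (is.null(bits)) 8L else as.integer(bits)
    px <- array(as.numeric(img), dim(img))   # drop the reader's attributes
  } else if (ext %in% c("jpg", "jpeg")) {
    img <- jpeg::readJPEG(path)
    bd <- 8L
    px <- img * 255
  } else stop(sprintf("unsupported image format: %s", ext))
  d <- dim(px)
  if (length(d) == 3L) {
    if (d[3] >= 3L) px <- px[, , 1:3] else px <- px[, , 1]
  }
  Frame(px, bd, metadata = metadata)
}

#' Write a Frame to an image file
#'
#' Format is chosen from the extension: PNG (8-bit), TIFF (8 or 16-bit,
#' matching the frame's bit depth) or JPEG.
#'
#' @param frame a \linkS4class{Frame}
#' @param path destination path
#' @return the path, invisibly
#' @export
writeFrame <- function(frame, path) {
  if (!is(frame, "Frame")) stop("frame must be a Frame")
  ext <- .fileExt(path)
  norm <- frame@pixels / maxValue(frame)
  norm <- .clip(norm, 0, 1)
  if (ext == "png") {
    png::writePNG(norm, path)
  } else if (ext %in% c("tif", "tiff")) {
    bits <- if (frame@bitDepth > 8L) 16L else 8L
    tiff::writeTIFF(norm, path, bits.per.sample = bits)
  } else if (ext %in% c("jpg", "jpeg")) {
    jpeg::writeJPEG(norm, path, quality = 0.95)
  } else stop(sprintf("unsupported image format: %s", ext))
  invisible(path)
}

# --- directory manifests ---------------------------------------------------

.writeManifest <- function(dir, entries, extra = list()) {
  jsonlite::write_json(c(list(frames = entries), extra),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.readManifest <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop(sprintf("no manifest.json in %s", dir))
  jsonlite::read_json(mf, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}

#' Write a focus stack to a directory
#'
#' Frames are written as TIFF files plus a \code{manifest.json} recording
#' filenames and z positions (and any exposure/timestamp metadata).
#'
#' @param stack a \linkS4class{FocusStack}
#' @param dir destination directory (created if missing)
#' @return the directory, invisibly
#' @export
writeFocusStack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(stack@frames)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    fn <- sprintf("layer_%03d.tiff", i)
    writeFrame(stack@frames[[i]], file.path(dir, fn))
    entries[[i]] <- list(file = fn, z_um = stack@z[i])
  }
  .writeManifest(dir, entries)
  invisible(dir)
}

#' Read a focus stack from a directory with a manifest
#' @param dir directory containing frames and \code{manifest.json} with
#'   \code{file} and \code{z_um} per frame
#' @return a \linkS4class{FocusStack}
#' @export
readFocusStack <- function(dir) {
  mf <- .readManifest(dir)
  fr <- mf$frames
  ord <- order(fr$z_um)
  fr <- fr[ord, , drop = FALSE]
  frames <- lapply(seq_len(nrow(fr)), function(i)
    readFrame(file.path(dir, fr$file[i]),
              metadata = list(z_position_um = fr$z_um[i])))
  FocusStack(frames, fr$z_um)
}

#' Write a timelapse series to a directory
#' @param series a \linkS4class{TimelapseSeries}
#' @param dir destination directory
#' @return the directory, invisibly
#' @export
writeTimelapse <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(series@frames)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    fn <- sprintf("frame_%05d.tiff", i)
    writeFrame(series@frames[[i]], file.path(dir, fn))
    e <- list(file = fn, timestamp_s = series@timestamps[i])
    ex <- series@frames[[i]]@metadata$exposure_ms
    if (!is.null(ex)) e$exposure_ms <- ex
    entries[[i]] <- e
  }
  .writeManifest(dir, entries)
  invisible(dir)
}

#' Read a timelapse series from a directory with a manifest
#' @param dir directory containing frames and \code{manifest.json} with
#'   \code{file} and \code{timestamp_s} per frame (optional
#'   \code{exposure_ms})
#' @return a \linkS4class{TimelapseSeries}
#' @export
readTimelapse <- function(dir) {
  mf <- .readManifest(dir)
  fr <- mf$frames
  ord <- order(fr$timestamp_s)
  fr <- fr[ord, , drop = FALSE]
  frames <- lapply(seq_len(nrow(fr)), function(i) {
    md <- list(timestamp_s = fr$timestamp_s[i])
    if ("exposure_ms" %in% names(fr) && !is.na(fr$exposure_ms[i]))
      md$exposure_ms <- fr$exposure_ms[i]
    readFrame(file.path(dir, fr$file[i]), metadata = md)
  })
  TimelapseSeries(frames, fr$timestamp_s)
}

#' Read a directory of bracketed frames
#'
#' Reads every frame named in the manifest with its \code{exposure_ms}
#' metadata, for \code{\link{selectBestExposure}}.
#'
#' @param dir directory with \code{manifest.json}
#' @return list of \linkS4class{Frame}
#' @export
readFrameSet <- function(dir) {
  mf <- .readManifest(dir)
  fr <- mf$frames
  lapply(seq_len(nrow(fr)), function(i) {
    md <- list()
    if ("exposure_ms" %in% names(fr) && !is.na(fr$exposure_ms[i]))
      md$exposure_ms <- fr$exposure_ms[i]
    readFrame(file.path(dir, fr$file[i]), metadata = md)
  })
}

# --- tabular I/O -----------------------------------------------------------

#' Write a sharpness curve as CSV (columns z_um, score)
#' @param curve a \linkS4class{SharpnessCurve}
#' @param path destination CSV path
#' @return the path, invisibly
#' @export
writeSharpnessCurve <- function(curve, path) {
  utils::write.csv(data.frame(z_um = curve@z, score = curve@score),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a spectrum as CSV
#'
#' Columns \code{position_px, r, g, b, lum} and \code{wavelength_nm} when
#' calibrated.
#'
#' @param s a \linkS4class{Spectrum}
#' @param path destination CSV path
#' @return the path, invisibly
#' @export
writeSpectrumCsv <- function(s, path) {
  df <- data.frame(position_px = s@position,
                   r = s@intensity[, "r"], g = s@intensity[, "g"],
                   b = s@intensity[, "b"], lum = s@intensity[, "lum"])
  if (length(s@wavelength)) df$wavelength_nm <- s@wavelength
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum from CSV (inverse of \code{\link{writeSpectrumCsv}})
#' @param path CSV path
#' @return a \linkS4class{Spectrum}
#' @export
readSpectrumCsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read spectrum: %s", path))
  df <- utils::read.csv(path)
  Spectrum(position = df$position_px,
           intensity = cbind(r = df$r, g = df$g, b = df$b, lum = df$lum),
           wavelength = if ("wavelength_nm" %in% names(df))
             df$wavelength_nm else numeric(0))
}

#' Write a wavelength calibration as JSON
#' @param cal a \linkS4class{WavelengthCalibration}
#' @param path destination JSON path
#' @return the path, invisibly
#' @export
writeCalibration <- function(cal, path) {
  jsonlite::write_json(list(coefficients = cal@coefficients,
                            rms_residual_nm = cal@rmsResidual,
                            n_points = cal@nPoints),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a wavelength calibration from JSON
#' @param path JSON path written by \code{\link{writeCalibration}}
#' @return a \linkS4class{WavelengthCalibration}
#' @export
readCalibration <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read calibration: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("WavelengthCalibration", coefficients = as.numeric(j$coefficients),
      rmsResidual = as.numeric(j$rms_residual_nm),
      nPoints = as.integer(j$n_points))
}
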