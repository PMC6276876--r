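#' Calibrated 3D intensity volume
#'
#' An `image_stack` wraps a numeric 3D array of fluorescence intensities with
#' its physical calibration. The array is indexed `[y, x, z]`; slice `z = 1`
#' is the apical-most plane and z increases toward the cell base, matching
#' the apical-to-basal acquisition direction of an inverted microscope
#' imaging an embryo surface. On disk (see [read_stack()]) the z slices are
#' the pages of a multi-page TIFF.
#'
#' @param data numeric 3D array `[y, x, z]` (a 2D matrix is promoted to a
#'   single-slice stack).
#' @param pixel_size lateral pixel size in micrometers.
#' @param dz axial slice spacing in micrometers.
#' @param channel role of the channel, `"membrane"` or `"myosin"`.
#' @param t acquisition time in seconds (optional, `NA` if unknown).
#'
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size, dz, channel = c("membrane", "myosin"),
                        t = NA_real_) {
  channel <- match.arg(channel)
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L) stop("'data' must be a 2D matrix or 3D array [y, x, z]")
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("'pixel_size' must be > 0")
  if (!is.numeric(dz) || dz <= 0) stop("'dz' must be > 0")
  structure(
    list(data = data, pixel_size = pixel_size, dz = dz,
         channel = channel, t = t),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack [%s]: %d x %d px (%.3g um/px), %d z-slices (dz %.3g um)%s\n",
              x$channel, d[1], d[2], x$pixel_size, d[3], x$dz,
              if (is.na(x$t)) "" else sprintf(", t = %.4g s", x$t)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' z positions of the slices of a stack, in micrometers
#'
#' @param stack an [image_stack()] (or a compatible list with `data` and `dz`).
#' @return numeric vector, `0, dz, 2*dz, ...` (apical slice at 0).
#' @export
z_positions <- function(stack) {
  (seq_len(dim(stack$data)[3]) - 1) * stack$dz
}

#' Read a multi-page TIFF as an image stack
#'
#' Pages are interpreted as z-slices (apical first). Stacks written by
#' [write_stack()] with intensities outside `[0, 1]` carry their rescaling
#' factor in a plain-text `<path>.scale` sidecar and are restored to
#' original units.
#'
#' @param path TIFF file path.
#' @inheritParams image_stack
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size, dz, channel = "membrane", t = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  sidecar <- paste0(path, ".scale")
  if (file.exists(sidecar)) {
    sc <- as.numeric(readLines(sidecar, n = 1))
    if (is.finite(sc)) arr <- arr * sc
  }
  image_stack(arr, pixel_size = pixel_size, dz = dz, channel = channel, t = t)
}

#' Write an image stack as a multi-page 32-bit TIFF
#'
#' Samples are stored at 32-bit depth (quantization about 2e-10 of full
#' scale). Intensities above 1 are divided by their maximum before storage
#' (the writer defines samples on `[0, 1]`) and the factor is recorded in
#' a plain-text `<path>.scale` sidecar so that [read_stack()] restores the
#' original units; negative intensities are clipped to 0 with a warning.
#'
#' @param stack an [image_stack()] or numeric 3D array.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  arr <- if (inherits(stack, "image_stack")) stack$data else stack
  sidecar <- paste0(path, ".scale")
  if (file.exists(sidecar)) unlink(sidecar)
  if (min(arr) < 0) {
    warning("negative intensities clipped to 0 (TIFF float samples are unsigned here)")
    arr[arr < 0] <- 0
  }
  if (max(arr) > 1) {
    sc <- max(arr)
    arr <- arr / sc
    writeLines(sprintf("%.17g", sc), sidecar)
  }
  pages <- lapply(seq_len(dim(arr)[3]), function(z) arr[, , z])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' Write a data frame as a CSV table
#'
#' UTF-8, header row, '.' decimal separator. Optional key-value comment
#' lines (prefixed `#`) record provenance such as the RNG seed and config
#' hash of a pipeline run.
#'
#' @param table a data.frame.
#' @param path output path.
#' @param meta named character/numeric vector written as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, meta = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(meta)) {
    writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  }
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV table written by [write_table()]
#'
#' @param path CSV path.
#' @return data.frame (comment lines are skipped).
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, comment.char = "#")
}
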