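#' Raster image container
#'
#' A thin S3 wrapper around a numeric matrix of intensities in `[0, 1]`,
#' indexed `(row, col)` with row 1 at the top of the page. All pipeline
#' stages operate on this representation.
#'
#' @param pixels Numeric matrix with values in `[0, 1]`.
#' @return An object of class `ecg_raster` (a numeric matrix).
#' @export
raster_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    abort_ecg("ecg_input_error", "pixels must be a numeric matrix")
  if (nrow(pixels) < 50L || ncol(pixels) < 50L)
    abort_ecg("ecg_size_error", sprintf(
      "image is %dx%d; at least 50x50 required", nrow(pixels), ncol(pixels)))
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    abort_ecg("ecg_input_error", "intensities must lie in [0, 1] and be non-missing")
  structure(pixels, class = c("ecg_raster", "matrix", "array"))
}

as_pixel_matrix <- function(img) {
  m <- unclass(img)
  attr(m, "class") <- NULL
  m
}

#' @export
print.ecg_raster <- function(x, ...) {
  cat(sprintf("<ecg_raster> %d x %d, intensity range [%.3f, %.3f]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Load an ECG page image
#'
#' Reads a PNG or JPEG file (8-bit grayscale or RGB), converts color input
#' to luminance with Rec.601 weights (0.299, 0.587, 0.114), and returns an
#' [raster_image()] with intensities in `[0, 1]`.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return An `ecg_raster`.
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    abort_ecg("ecg_input_error", sprintf("cannot read image file '%s'", path))
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           jpg = ,
           jpeg = jpeg::readJPEG(path),
           abort_ecg("ecg_input_error", sprintf(
             "unsupported image format '%s' for '%s' (PNG or JPEG expected)", ext, path))),
    error = function(e) {
      if (inherits(e, "ecg_error")) stop(e)
      abort_ecg("ecg_input_error", sprintf("failed to decode '%s': %s", path, conditionMessage(e)))
    })
  raster_image(luminance(arr))
}

# Collapse a readPNG/readJPEG array to one luminance channel.
luminance <- function(arr) {
  if (is.matrix(arr)) return(arr)
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    if (nch == 1L) return(arr[, , 1L])
    if (nch >= 3L)
      return(0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L])
    if (nch == 2L) return(arr[, , 1L]) # gray + alpha
  }
  abort_ecg("ecg_input_error", "unrecognized image array layout")
}

#' Write a raster image to disk
#'
#' @param img An `ecg_raster` (or plain matrix in `[0, 1]`).
#' @param path Output path; format chosen by extension (`.png`, `.jpg`).
#' @param jpeg_quality JPEG quality in `(0, 1]`, ignored for PNG.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path, jpeg_quality = 0.92) {
  m <- pmin(pmax(as_pixel_matrix(img), 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(m, path),
         jpg = ,
         jpeg = jpeg::writeJPEG(m, path, quality = jpeg_quality),
         abort_ecg("ecg_input_error", sprintf("unsupported output format '%s'", ext)))
  invisible(path)
}

#' Attenuate isolated specks with a 3x3 median filter
#'
#' The preprocessing filter: a 3x3 sliding-window median with edge
#' replication. Single-pixel noise is removed while the extended dark
#' structures of the printed traces (>= 2 px wide) are preserved.
#'
#' @param img An `ecg_raster`.
#' @return A filtered `ecg_raster` of identical dimensions.
#' @export
denoise <- function(img) {
  m <- as_pixel_matrix(img)
  raster_image(.cpp_median3x3(m))
}

#' Page layout configuration
#'
#' Describes how many leads the printed record carries and how they are
#' arranged (two half-page columns of `leads_per_column` leads, plus an
#' optional full-width rhythm strip at the bottom when `n_leads = 13`).
#'
#' @param n_leads 12 or 13.
#' @param leads_per_column Leads per printed column (default 6).
#' @param rhythm_lead Label of the long rhythm-strip lead (required when
#'   `n_leads = 13`), conventionally `"II"`.
#' @return An object of class `ecg_layout`.
#' @export
layout_config <- function(n_leads = 13L, leads_per_column = 6L,
                          rhythm_lead = if (n_leads == 13L) "II" else NULL) {
  if (!n_leads %in% c(12L, 13L))
    abort_ecg("ecg_param_error", "n_leads must be 12 or 13")
  if (n_leads == 13L && (is.null(rhythm_lead) || !nzchar(rhythm_lead)))
    abort_ecg("ecg_param_error", "a 13-lead layout requires rhythm_lead")
  structure(list(n_leads = as.integer(n_leads),
                 leads_per_column = as.integer(leads_per_column),
                 rhythm_lead = rhythm_lead),
            class = "ecg_layout")
}

#' Bounding box (1-based, inclusive)
#'
#' @param row_start,row_end,col_start,col_end Pixel indices, 1-based,
#'   inclusive on both ends.
#' @return An object of class `ecg_box`.
#' @export
bounding_box <- function(row_start, row_end, col_start, col_end) {
  v <- c(row_start, row_end, col_start, col_end)
  if (anyNA(v) || row_start < 1 || col_start < 1 ||
      row_end < row_start || col_end < col_start)
    abort_ecg("ecg_param_error", "invalid bounding box")
  structure(list(row_start = as.integer(row_start), row_end = as.integer(row_end),
                 col_start = as.integer(col_start), col_end = as.integer(col_end)),
            class = "ecg_box")
}

#' @rdname bounding_box
#' @param box An `ecg_box`.
#' @export
box_height <- function(box) box$row_end - box$row_start + 1L

#' @rdname bounding_box
#' @export
box_width <- function(box) box$col_end - box$col_start + 1L

#' Crop an image to a bounding box
#'
#' @param img An `ecg_raster`.
#' @param box An `ecg_box` lying within the image.
#' @return The cropped `ecg_raster` (plain matrix if smaller than 50x50).
#' @export
crop_box <- function(img, box) {
  m <- as_pixel_matrix(img)
  if (box$row_end > nrow(m) || box$col_end > ncol(m))
    abort_ecg("ecg_param_error", "box exceeds image extent")
  m[box$row_start:box$row_end, box$col_start:box$col_end, drop = FALSE]
}
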