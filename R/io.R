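#' Read a binary vessel mask from a raster file
#'
#' Supports PNG and portable anymaps (PBM/PGM/PPM).  Multi-channel or
#' high-bit-depth images are reduced by the nonzero-anywhere rule: a pixel
#' is foreground if any channel is nonzero.  TIFF is not supported (no
#' reader available); convert to PNG first.
#'
#' @param path path to a PNG/PBM/PGM/PPM file.
#' @return an `"av_mask"`.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    pbm = , pgm = , ppm = , pnm = pixmap::getChannels(pixmap::read.pnm(path)),
    tif = , tiff = stop("TIFF is not supported; convert to PNG"),
    stop("unsupported raster format: .", ext)
  )
  if (length(dim(arr)) == 3L) arr <- apply(arr != 0, c(1, 2), any)
  if (!all(dim(arr) >= 1L) || length(arr) == 0L) stop("zero-size image: ", path)
  as_mask(arr != 0)
}

#' Write a binary mask or skeleton to PNG
#'
#' @param mask mask/skeleton/logical matrix.
#' @param path output path (.png).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  g <- as_binary_grid(mask)
  png::writePNG(g * 1, path)
  invisible(path)
}

#' Write descriptor records to CSV
#'
#' Fixed header `image_id, op_alpha_min, op_area, vs, grad_alpha, fd,
#' group_label`; numbers at full (round-trip) precision; missing FD becomes
#' an empty cell, not 0.
#'
#' @param records list of `"descriptor_record"`s or a data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(records, path) {
  df <- if (is.data.frame(records)) records else records_to_frame(records)
  if (!nrow(df)) stop("no records to write")
  cols <- c("image_id", "op_alpha_min", "op_area", "vs", "grad_alpha", "fd",
            "group_label")
  for (col in setdiff(cols, names(df))) df[[col]] <- NA
  df <- df[, cols]
  fmt <- function(v) {
    if (is.numeric(v)) ifelse(is.na(v), "", sprintf("%.17g", v))
    else ifelse(is.na(v), "", as.character(v))
  }
  out <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, cols))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con)
  writeLines(apply(out, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' Read a descriptor CSV written by [write_descriptors()]
#' @param path CSV path.
#' @return data.frame with the fixed descriptor columns.
#' @export
read_descriptors <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(image_id = "character",
                                group_label = "character"))
  for (col in c("op_alpha_min", "op_area", "vs", "grad_alpha", "fd"))
    df[[col]] <- as.numeric(df[[col]])
  df
}
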