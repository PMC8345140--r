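#' Read an RGB image patch
#'
#' Reads a PNG or TIFF image into an 8-bit-scaled numeric array
#' (H x W x 3, values 0-255, origin top-left, row-major).
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return numeric array `H x W x 3` with values in 0-255.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", path)
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Write an RGB image patch as PNG
#'
#' @param image numeric array H x W x 3 with values in 0-255.
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  png::writePNG(clip(image / 255, 0, 1), path)
  invisible(path)
}

#' Read an instance label map or binary mask
#'
#' Masks are stored as single-channel 16-bit PNG (or TIFF) where the pixel
#' value is the instance label (0 = background).
#'
#' @param path path to the mask file.
#' @return integer matrix of labels.
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported mask format: ", path)
  )
  if (length(dim(m)) == 3L) m <- m[, , 1]
  out <- round(m * 65535)
  storage.mode(out) <- "integer"
  out
}

#' Write an instance label map as 16-bit TIFF
#'
#' @param labels integer matrix (0 = background, k > 0 = instance k).
#' @param path output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(labels, path) {
  if (any(labels < 0)) stop("labels must be non-negative")
  if (any(labels > 65535)) stop("labels exceed 16-bit range")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read / write a cohort table
#'
#' Cohort CSV files carry the columns
#' `patient_id,density,area_mm2,time_years,event` (plus any extras).
#'
#' @param path CSV file path.
#' @return `read_cohort`: a data.frame.
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "density", "area_mm2", "time_years", "event")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("cohort file missing columns: ", paste(miss, collapse = ", "))
  x
}

#' @rdname read_cohort
#' @param cohort data.frame as produced by [generate_cohort()].
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
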