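#' Read and write sinograms and images
#'
#' Plain-text round trip for the package's array objects: sinogram values
#' and image matrices go to CSV (one row per detector / image row); the
#' sinogram metadata (domain, geometry, sampling) goes to a JSON sidecar.
#'
#' @param s A `pat_sinogram`.
#' @param path Output CSV path; the sidecar is `<path>.json`.
#' @return `write_sinogram` invisibly returns `path`; `read_sinogram`
#'   returns a `pat_sinogram`.
#' @export
write_sinogram <- function(s, path) {
  stopifnot(inherits(s, "pat_sinogram"))
  utils::write.table(s$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(
    domain = s$domain,
    geometry = s$geom[setdiff(names(s$geom), "positions")],
    positions = unname(apply(s$geom$positions, 1, as.numeric, simplify = FALSE)),
    sampling = list(c = s$sampling$c, dt = s$sampling$dt,
                    n_samples = s$sampling$n_samples)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  values <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(values) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  geom <- meta$geometry
  geom$positions <- as.matrix(meta$positions)
  class(geom) <- "scan_geometry"
  sampling <- make_sampling(meta$sampling$c, meta$sampling$dt,
                            meta$sampling$n_samples)
  sinogram(values, meta$domain, geom, sampling)
}

#' Load a grayscale image from PNG or TIFF
#'
#' Reads a raster image (via the `png`/`tiff` packages), converts RGB to
#' luminance if needed, transposes to the package's `A[i, j]` (x, y)
#' convention and normalizes to `[0, 1]`.
#'
#' @param path Image file path (`.png`, `.tif`, `.tiff`).
#' @return Image matrix in `[0, 1]`.
#' @export
load_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("package `png` is required to read PNG files", call. = FALSE)
      png::readPNG(path)
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("package `tiff` is required to read TIFF files", call. = FALSE)
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  if (length(dim(raw)) == 3) {
    raw <- 0.2126 * raw[, , 1] + 0.7152 * raw[, , 2] + 0.0722 * raw[, , 3]
  }
  # raster rows run top-to-bottom along y; flip to y-up, x along rows
  normalize_image(t(raw[rev(seq_len(nrow(raw))), , drop = FALSE]))
}

#' Write an image matrix as 8-bit PNG
#'
#' Normalizes to `[0, 1]` (negatives clipped) and writes an 8-bit grayscale
#' PNG for visual inspection.
#'
#' @param A Image matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_image_png <- function(A, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("package `png` is required to write PNG files", call. = FALSE)
  An <- normalize_image(pmax(unclass(A), 0))
  raster <- t(An)[rev(seq_len(ncol(An))), , drop = FALSE]
  png::writePNG(raster, path)
  invisible(path)
}
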