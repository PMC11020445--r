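#' 2-D grayscale image with physical pixel spacing
#'
#' The substrate for all intensity measurement: a numeric matrix of
#' nonnegative pixel values (row 1 at the top) plus an isotropic pixel
#' spacing in millimetres. All annotation geometry lives in continuous mm
#' coordinates with x increasing rightwards (columns) and y increasing
#' downwards (rows); the centre of pixel `(i, j)` (1-based) is at
#' `((j - 0.5) * spacing, (i - 0.5) * spacing)`.
#'
#' @param pixels numeric matrix of nonnegative intensities, no missing values.
#' @param spacing_mm positive scalar, mm per pixel (isotropic).
#' @return An object of class `ebq_image` (a list with elements `pixels`
#'   and `spacing_mm`).
#' @examples
#' img <- image2d(matrix(100, 32, 32), spacing_mm = 0.5)
#' dim(img$pixels)
#' @export
image2d <- function(pixels, spacing_mm) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(pixels)) stop("`pixels` must not contain missing values", call. = FALSE)
  if (any(pixels < 0)) stop("`pixels` must be nonnegative", call. = FALSE)
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0) {
    stop("`spacing_mm` must be a single positive number", call. = FALSE)
  }
  structure(list(pixels = pixels, spacing_mm = as.numeric(spacing_mm)),
            class = "ebq_image")
}

#' @export
print.ebq_image <- function(x, ...) {
  cat(sprintf("<ebq_image> %d x %d px @ %g mm/px (%.1f x %.1f mm)\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing_mm,
              nrow(x$pixels) * x$spacing_mm, ncol(x$pixels) * x$spacing_mm))
  invisible(x)
}

is_image2d <- function(x) inherits(x, "ebq_image")

# mm coordinates of all pixel centres; columns x, y in row-major pixel order
pixel_centres <- function(image) {
  s <- image$spacing_mm
  nr <- nrow(image$pixels)
  nc <- ncol(image$pixels)
  list(
    x = rep((seq_len(nc) - 0.5) * s, each = nr),
    y = rep((seq_len(nr) - 0.5) * s, times = nc),
    nr = nr, nc = nc
  )
}

#' Read a 2-D grayscale image
#'
#' Reads PNG, TIFF, or single-slice NIfTI images into an [image2d()] object.
#' NIfTI carries its pixel spacing in the header (it must be isotropic in
#' the slice plane); PNG and TIFF take the spacing from a JSON side-car file
#' (`<path>.json` with at least `{"spacing_mm": s}`, optionally an
#' `"intensity_scale"` by which the unit-range samples are multiplied) or
#' from the `spacing_mm` argument, which takes precedence.
#'
#' @param path image file (`.png`, `.tif(f)`, `.nii`, `.nii.gz`).
#' @param spacing_mm optional spacing override in mm/pixel.
#' @return An `ebq_image`.
#' @seealso [write_image()]
#' @export
read_image <- function(path, spacing_mm = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    d <- dim(arr)
    if (length(d) > 2L) {
      if (prod(d[-(1:2)]) != 1L) {
        stop("NIfTI image is not a single slice: dims ", paste(d, collapse = "x"),
             call. = FALSE)
      }
      dim(arr) <- d[1:2]
    }
    arr <- matrix(as.numeric(arr), nrow(arr), ncol(arr))  # drop nifti attributes
    pd <- RNifti::pixdim(img)[1:2]
    if (abs(pd[1] - pd[2]) > 1e-9) {
      stop(sprintf("anisotropic pixel spacing unsupported: %g x %g mm", pd[1], pd[2]),
           call. = FALSE)
    }
    sp <- if (is.null(spacing_mm)) pd[1] else spacing_mm
    # NIfTI stores x (columns of our matrix) as the first array dimension
    return(image2d(t(arr), sp))
  }
  if (grepl("\\.png$", lower) || grepl("\\.tiff?$", lower)) {
    arr <- if (grepl("\\.png$", lower)) png::readPNG(path) else tiff::readTIFF(path)
    if (length(dim(arr)) == 3L) arr <- arr[, , 1L]  # grayscale written as RGB
    scale <- 1
    sp <- spacing_mm
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      if (is.null(sp)) sp <- meta$spacing_mm
      if (!is.null(meta$intensity_scale)) scale <- meta$intensity_scale
    }
    if (is.null(sp)) {
      stop("pixel spacing missing: supply `spacing_mm` or a side-car ", sidecar,
           call. = FALSE)
    }
    return(image2d(arr * scale, sp))
  }
  stop("unknown image format: ", path, " (expected .png, .tif(f), .nii[.gz])",
       call. = FALSE)
}

#' Write a 2-D grayscale image
#'
#' NIfTI output stores the pixel grid as doubles with the spacing in the
#' header and round-trips bit-identically through [read_image()]. PNG output
#' is 8-bit: intensities are scaled to the unit range and the scale factor
#' (the intensity maximum rounded up) is recorded in the JSON side-car
#' together with the spacing. TIFF output uses 32-bit float samples.
#'
#' @param image an `ebq_image`.
#' @param path output file; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(is_image2d(image))
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    arr <- t(image$pixels)  # back to x-first storage
    nif <- RNifti::asNifti(arr)
    RNifti::pixdim(nif) <- c(image$spacing_mm, image$spacing_mm)
    RNifti::writeNifti(nif, path, datatype = "double")
    return(invisible(path))
  }
  if (grepl("\\.png$", lower) || grepl("\\.tiff?$", lower)) {
    mx <- max(image$pixels, 1)
    scale <- ceiling(mx)
    if (grepl("\\.png$", lower)) {
      png::writePNG(image$pixels / scale, path)
    } else {
      tiff::writeTIFF(image$pixels / scale, path, bits.per.sample = 32L)
    }
    jsonlite::write_json(
      list(spacing_mm = image$spacing_mm, intensity_scale = scale),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  stop("unknown image format: ", path, call. = FALSE)
}
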