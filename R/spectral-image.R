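#' Hyperspectral image container
#'
#' A wavenumber-indexed absorbance cube with pixel geometry: the basic
#' currency of the IR-imaging half of the package.
#'
#' @param absorbance Numeric array `rows x cols x wavenumbers` (a matrix is
#'   treated as a single-pixel-row image), in absorbance units.
#' @param wavenumbers Strictly monotone numeric vector, 1/cm. Stored
#'   ascending internally; the original order is remembered for file output.
#' @param pixel_size Pixel edge length, micrometres.
#' @param provenance One of `"FTIR"`, `"QCL"`, `"synthetic"`.
#' @return A `spectral_image` object.
#' @export
spectral_image <- function(absorbance, wavenumbers, pixel_size,
                           provenance = "synthetic") {
  if (is.matrix(absorbance)) {
    absorbance <- array(absorbance, c(1, dim(absorbance)))
  }
  stopifnot(
    length(dim(absorbance)) == 3,
    dim(absorbance)[3] == length(wavenumbers),
    pixel_size > 0
  )
  if (!all(is.finite(absorbance))) {
    stop("absorbance values must be finite", call. = FALSE)
  }
  d <- diff(wavenumbers)
  if (!(all(d > 0) || all(d < 0))) {
    stop("wavenumber vector must be strictly monotone", call. = FALSE)
  }
  descending <- d[1] < 0
  if (descending) {
    wavenumbers <- rev(wavenumbers)
    absorbance <- absorbance[, , rev(seq_along(wavenumbers)), drop = FALSE]
  }
  provenance <- match.arg(provenance, c("FTIR", "QCL", "synthetic"))
  structure(
    list(
      absorbance = absorbance,
      wavenumbers = wavenumbers,
      pixel_size = pixel_size,
      provenance = provenance,
      file_order_descending = descending
    ),
    class = "spectral_image"
  )
}

#' @export
print.spectral_image <- function(x, ...) {
  d <- dim(x$absorbance)
  cat(
    "<spectral_image> ", d[1], "x", d[2], " px (", x$pixel_size,
    " um), ", d[3], " wavenumbers ", min(x$wavenumbers), "-",
    max(x$wavenumbers), " 1/cm [", x$provenance, "]\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn spectral_image Number of pixels `c(rows, cols)`.
#' @param image A `spectral_image`.
#' @export
image_dim <- function(image) {
  stopifnot(inherits(image, "spectral_image"))
  dim(image$absorbance)[1:2]
}

#' @describeIn spectral_image Pixel spectra as an `n_pixels x n_wavenumbers`
#'   matrix (pixels in column-major order).
#' @export
as_spectra_matrix <- function(image) {
  stopifnot(inherits(image, "spectral_image"))
  d <- dim(image$absorbance)
  matrix(image$absorbance, d[1] * d[2], d[3])
}

#' Read and write hyperspectral cubes
#'
#' Cubes are stored as multi-frame 32-bit TIFF (one frame per wavenumber)
#' with a JSON sidecar (`<path>.json`) holding the wavenumber vector,
#' pixel size, provenance and the affine intensity encoding used to fit the
#' absorbance range into TIFF's unit interval.
#'
#' @param image A [spectral_image()].
#' @param path TIFF file path; the sidecar is written next to it.
#' @return `write_spectral_image()` returns `path` invisibly;
#'   `read_spectral_image()` the restored `spectral_image`.
#' @export
write_spectral_image <- function(image, path) {
  stopifnot(inherits(image, "spectral_image"))
  rng <- range(image$absorbance)
  scale <- max(rng[2] - rng[1], 1e-300)
  frames_idx <- seq_along(image$wavenumbers)
  wn_out <- image$wavenumbers
  if (image$file_order_descending) {
    frames_idx <- rev(frames_idx)
    wn_out <- rev(wn_out)
  }
  frames <- lapply(frames_idx, function(k) {
    (image$absorbance[, , k] - rng[1]) / scale
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 32, reduce = FALSE)
  meta <- list(
    wavenumbers_cm1 = wn_out,
    pixel_size_um = image$pixel_size,
    provenance = image$provenance,
    intensity_offset = rng[1],
    intensity_scale = scale
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_spectral_image
#' @export
read_spectral_image <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- tiff::readTIFF(path, all = TRUE)
  cube <- array(
    0, c(dim(frames[[1]])[1], dim(frames[[1]])[2], length(frames))
  )
  for (k in seq_along(frames)) {
    cube[, , k] <- frames[[k]] * meta$intensity_scale + meta$intensity_offset
  }
  spectral_image(
    cube, meta$wavenumbers_cm1, meta$pixel_size_um,
    provenance = meta$provenance
  )
}

#' Read and write single-channel image maps as TIFF
#'
#' Used for quality masks, ground-truth masks, activation maps and
#' unsaturation maps. Logical matrices are stored as 0/1; numeric maps must
#' lie in `[0, 1]` (activation scores) or are min-max annotated via an
#' accompanying JSON sidecar when `normalize = TRUE`.
#'
#' @param map Numeric or logical matrix; `NA` written as 0 with a mask
#'   frame is not supported, use finite values.
#' @param path File path.
#' @param normalize Write arbitrary-range maps by affine-encoding into
#'   `[0, 1]` with a JSON sidecar.
#' @return `write_map_tiff()` returns `path` invisibly; `read_map_tiff()`
#'   the matrix (logical if the stored data are 0/1 and `logical = TRUE`).
#' @param logical Return a logical mask.
#' @export
write_map_tiff <- function(map, path, normalize = FALSE) {
  m <- map
  if (is.logical(m)) m <- m * 1
  if (normalize) {
    rng <- range(m)
    scale <- max(rng[2] - rng[1], 1e-300)
    jsonlite::write_json(
      list(intensity_offset = rng[1], intensity_scale = scale),
      paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA
    )
    m <- (m - rng[1]) / scale
  }
  if (any(m < 0 | m > 1)) {
    stop("map values outside [0,1]; use normalize = TRUE", call. = FALSE)
  }
  tiff::writeTIFF(m, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' @rdname write_map_tiff
#' @export
read_map_tiff <- function(path, logical = FALSE) {
  m <- tiff::readTIFF(path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    m <- m * meta$intensity_scale + meta$intensity_offset
  }
  if (logical) m <- m >= 0.5
  m
}
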