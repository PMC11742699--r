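#' Otsu's threshold
#'
#' Threshold maximizing the between-class variance over a 256-bin uniform
#' histogram of the observed value range. The foreground mask convention
#' throughout the package is `values >= threshold`.
#'
#' @param values Numeric vector or matrix with at least 2 distinct values.
#' @param n_bins Histogram bins (default 256).
#' @return The threshold (a bin edge).
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  v <- as.vector(values)
  v <- v[is.finite(v)]
  if (length(unique(v)) < 2) {
    stop("Otsu threshold undefined for constant input", call. = FALSE)
  }
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(
    pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1), n_bins),
    nbins = n_bins
  )
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w <- counts / sum(counts)
  omega <- cumsum(w) # class 0 = bins 1..k (below threshold edge k+1)
  mu <- cumsum(w * centers)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b2 <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, -Inf)
  k <- which.max(sigma_b2[-n_bins]) # cut after bin k
  edges[k + 1]
}

# nearest-neighbour resampling of a source image onto a target pixel grid
# through a source->target transform (pixel-center coordinates, 1-based)
resample_to_grid <- function(channel, transform, target_dim, fill = 0) {
  inv <- invert_transform(transform)
  grid <- cbind(
    x = rep(seq_len(target_dim[2]), each = target_dim[1]),
    y = rep(seq_len(target_dim[1]), target_dim[2])
  )
  src <- apply_transform(inv, grid)
  i <- round(src[, 2])
  j <- round(src[, 1])
  ok <- i >= 1 & i <= nrow(channel) & j >= 1 & j <= ncol(channel)
  out <- rep(fill, nrow(grid))
  out[ok] <- channel[cbind(i[ok], j[ok])]
  matrix(out, target_dim[1], target_dim[2])
}

disc_brush <- function(radius_px) {
  r <- max(1L, round(radius_px))
  d <- 2L * r + 1L
  xx <- matrix(rep(-r:r, d), d, d)
  (xx^2 + t(xx)^2 <= r^2) * 1
}

#' Plaque core, corona and surrounding-ring masks
#'
#' Registers two stain channels (fibril-core and pan-amyloid, e.g.
#' ThT-like and 4G8-like) onto the IR pixel grid, binarizes each with
#' Otsu's method, and derives three disjoint region masks: `core`
#' (fibril-positive), `corona` (amyloid-positive minus core) and
#' `surrounding_ring` (a band of `ring_width_px` pixels hugging the
#' plaque outline).
#'
#' @param core_channel,corona_channel Numeric matrices (stain images) in
#'   the source coordinate system.
#' @param transform A `transform2d` mapping source (x = col, y = row)
#'   pixel coordinates onto the IR grid; use an identity affine when the
#'   channels are already aligned.
#' @param ir_dim Target grid size `c(rows, cols)`.
#' @param ring_width_px Ring width in IR pixels (default rounds 10 um at
#'   the image's pixel size — pass explicitly).
#' @return A `region_masks` object: logical matrices `core`, `corona`,
#'   `surrounding_ring` (pairwise disjoint).
#' @export
make_region_masks <- function(core_channel, corona_channel, transform,
                              ir_dim, ring_width_px = 9) {
  core_r <- resample_to_grid(core_channel, transform, ir_dim)
  corona_r <- resample_to_grid(corona_channel, transform, ir_dim)
  core <- core_r >= otsu_threshold(core_r)
  corona_all <- corona_r >= otsu_threshold(corona_r)
  corona <- corona_all & !core
  plaque <- core | corona
  if (!any(plaque)) {
    warning("empty plaque mask; surrounding ring is empty", call. = FALSE)
    ring <- plaque
  } else {
    dil <- EBImage::dilate(
      EBImage::Image(plaque * 1), disc_brush(ring_width_px)
    ) > 0.5
    ring <- matrix(as.vector(dil), ir_dim[1], ir_dim[2]) & !plaque
  }
  structure(
    list(core = core, corona = corona, surrounding_ring = ring),
    class = "region_masks"
  )
}

#' @export
print.region_masks <- function(x, ...) {
  cat(
    "<region_masks> core ", sum(x$core), " px, corona ", sum(x$corona),
    " px, ring ", sum(x$surrounding_ring), " px\n",
    sep = ""
  )
  invisible(x)
}

#' Mean spectrum over a pixel mask
#'
#' Arithmetic mean of all pixel spectra inside the mask (optionally
#' restricted to quality-valid pixels): the region spectrum used to
#' compare plaque core, corona and surrounding tissue.
#'
#' @param image A [spectral_image()].
#' @param mask Logical matrix on the image grid.
#' @param quality Optional [quality_filter()] report.
#' @return Tibble with `wavenumber` and `absorbance`.
#' @export
region_mean_spectrum <- function(image, mask, quality = NULL) {
  stopifnot(inherits(image, "spectral_image"))
  d <- image_dim(image)
  stopifnot(all(dim(mask) == d))
  use <- as.vector(mask)
  if (!is.null(quality)) use <- use & as.vector(quality$valid)
  if (!any(use)) stop("empty mask (no valid pixels)", call. = FALSE)
  Y <- as_spectra_matrix(image)
  tibble::tibble(
    wavenumber = image$wavenumbers,
    absorbance = colMeans(Y[use, , drop = FALSE])
  )
}

#' Write a region spectrum as two-column CSV
#'
#' @param spectrum Tibble with `wavenumber`, `absorbance`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(all(c("wavenumber", "absorbance") %in% names(spectrum)))
  readr::write_csv(spectrum[, c("wavenumber", "absorbance")], path)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  readr::read_csv(path, col_types = "dd")
}
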