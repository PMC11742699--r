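#' Signal-to-noise ratio of a pixel spectrum
#'
#' SNR is defined as the maximum absorbance inside the signal window
#' (default 1600-1700 1/cm, the amide I region) divided by the standard
#' deviation of the residual after linear detrending inside a band-free
#' noise window. The default noise window is 1900-2100 1/cm for
#' full-range spectra and 980-1100 1/cm for fingerprint-only (QCL-range)
#' grids. A noise SD below 1e-12 returns `Inf` (noiseless spectrum).
#'
#' @param spectrum Numeric absorbance vector.
#' @param wavenumbers Matching wavenumber vector, 1/cm.
#' @param signal_window,noise_window Length-2 ranges, 1/cm.
#' @return Scalar SNR (possibly `Inf`).
#' @export
estimate_snr <- function(spectrum, wavenumbers,
                         signal_window = c(1600, 1700),
                         noise_window = NULL) {
  stopifnot(length(spectrum) == length(wavenumbers))
  if (is.null(noise_window)) {
    noise_window <- if (max(wavenumbers) >= 2100) {
      c(1900, 2100)
    } else {
      c(980, 1100)
    }
  }
  in_sig <- wavenumbers >= signal_window[1] & wavenumbers <= signal_window[2]
  in_noi <- wavenumbers >= noise_window[1] & wavenumbers <= noise_window[2]
  if (!any(in_sig)) stop("empty signal window", call. = FALSE)
  if (sum(in_noi) < 3) stop("empty (or too small) noise window", call. = FALSE)
  signal <- max(spectrum[in_sig])
  x <- wavenumbers[in_noi]
  y <- spectrum[in_noi]
  resid <- stats::lm.fit(cbind(1, x), y)$residuals
  noise <- stats::sd(resid)
  if (noise < 1e-12) {
    return(Inf)
  }
  signal / noise
}

#' Pixel quality filter: SNR and scatter exclusion
#'
#' Flags pixel spectra with high noise (SNR below `snr_min`, default 100)
#' or strong scattering. The scatter score is the EMSC baseline-coefficient
#' energy relative to the multiplicative coefficient (`||a||_2 / |b|`); by
#' default pixels in the top `1 - scatter_quantile` tail are excluded
#' (an absolute cutoff can be given instead via `scatter_max`). The
#' quantile rule is a documented stand-in for the unspecified "high
#' scattering" criterion.
#'
#' @param image A [spectral_image()].
#' @param snr_min SNR threshold; pixels below it are invalid.
#' @param scatter_max Absolute scatter-score cutoff; overrides the
#'   quantile rule when non-`NULL`.
#' @param scatter_quantile Quantile defining the scatter cutoff.
#' @param signal_window,noise_window Passed to [estimate_snr()].
#' @param poly_order EMSC baseline order for the scatter score.
#' @return A `quality_report`: matrices `snr`, `scatter_score`, `valid`,
#'   plus the applied cutoffs.
#' @export
quality_filter <- function(image, snr_min = 100, scatter_max = NULL,
                           scatter_quantile = 0.98,
                           signal_window = c(1600, 1700),
                           noise_window = NULL, poly_order = 2) {
  stopifnot(inherits(image, "spectral_image"))
  Y <- as_spectra_matrix(image) # npix x n_wn
  wn <- image$wavenumbers
  snr <- apply(Y, 1, estimate_snr,
    wavenumbers = wn,
    signal_window = signal_window, noise_window = noise_window
  )
  emsc <- emsc_fit_matrix(t(Y), colMeans(Y), wn, poly_order)
  scatter <- emsc$scatter_score
  cutoff <- if (is.null(scatter_max)) {
    stats::quantile(scatter, scatter_quantile, names = FALSE)
  } else {
    scatter_max
  }
  d <- image_dim(image)
  # an infinite snr_min is an unattainable cutoff: everything is invalid
  # (Inf >= Inf would otherwise pass for noiseless pixels)
  snr_ok <- if (is.infinite(snr_min)) rep(FALSE, length(snr)) else {
    snr >= snr_min
  }
  valid <- matrix(snr_ok & scatter <= cutoff, d[1], d[2])
  if (!any(valid)) {
    warning("all pixels failed the quality filter", call. = FALSE)
  }
  structure(
    list(
      snr = matrix(snr, d[1], d[2]),
      scatter_score = matrix(scatter, d[1], d[2]),
      valid = valid,
      snr_min = snr_min,
      scatter_cutoff = cutoff
    ),
    class = "quality_report"
  )
}

#' @export
print.quality_report <- function(x, ...) {
  cat(
    "<quality_report> ", sum(x$valid), "/", length(x$valid),
    " pixels valid (snr_min = ", x$snr_min, ", scatter cutoff = ",
    signif(x$scatter_cutoff, 4), ")\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn quality_filter One row per pixel with `row`, `col`, `snr`,
#'   `scatter_score`, `valid`.
#' @param x A `quality_report`.
#' @param ... Unused.
#' @export
tidy.quality_report <- function(x, ...) {
  d <- dim(x$snr)
  tibble::tibble(
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    snr = as.vector(x$snr),
    scatter_score = as.vector(x$scatter_score),
    valid = as.vector(x$valid)
  )
}
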