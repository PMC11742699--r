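# Legendre polynomials P_0..P_order on x in [-1, 1], as columns
legendre_basis <- function(x, order) {
  stopifnot(order >= 0)
  out <- matrix(0, length(x), order + 1)
  out[, 1] <- 1
  if (order >= 1) out[, 2] <- x
  if (order >= 2) {
    for (n in 1:(order - 1)) {
      out[, n + 2] <- ((2 * n + 1) * x * out[, n + 1] - n * out[, n]) / (n + 1)
    }
  }
  out
}

emsc_design <- function(reference, wavenumbers, poly_order, extra_basis) {
  x <- 2 * (wavenumbers - min(wavenumbers)) /
    (max(wavenumbers) - min(wavenumbers)) - 1
  X <- cbind(reference, legendre_basis(x, poly_order))
  if (!is.null(extra_basis)) X <- cbind(X, extra_basis)
  X
}

# least-squares EMSC of many spectra at once; Y is n_wn x n_spec
emsc_fit_matrix <- function(Y, reference, wavenumbers, poly_order = 2,
                            extra_basis = NULL) {
  X <- emsc_design(reference, wavenumbers, poly_order, extra_basis)
  coef <- qr.coef(qr(X), Y) # p x n_spec
  coef[is.na(coef)] <- 0
  fitted <- X %*% coef
  residual <- Y - fitted
  b <- coef[1, ]
  additive <- X[, -1, drop = FALSE] %*% coef[-1, , drop = FALSE]
  corrected <- sweep(Y - additive, 2, b, `/`)
  list(
    b = b,
    baseline_coeffs = coef[-1, , drop = FALSE],
    corrected = corrected,
    residual_norm = sqrt(colSums(residual^2)),
    scatter_score = sqrt(colSums(coef[-1, , drop = FALSE]^2)) / abs(b)
  )
}

#' Extended multiplicative signal correction (EMSC)
#'
#' Separates multiplicative (path length / scatter) and additive (smooth
#' baseline) effects by ordinary least squares of the raw spectrum on a
#' reference spectrum plus Legendre polynomials of the scaled wavenumber:
#' `raw ~ b * reference + sum_k a_k P_k(x)`, `x` mapped to `[-1, 1]`.
#' The corrected spectrum is `(raw - sum_k a_k P_k) / b`. Extra basis
#' vectors (e.g. tabulated Mie extinction curves) may be appended; none
#' are shipped.
#'
#' @param spectrum Numeric vector, absorbance on the grid of `wavenumbers`.
#' @param reference Reference spectrum on the same grid (typically the mean
#'   of valid pixel spectra).
#' @param wavenumbers Wavenumber vector, 1/cm.
#' @param poly_order Order of the Legendre baseline (default 2).
#' @param extra_basis Optional matrix of additional basis columns.
#' @return An `emsc_result`: `b` (multiplicative coefficient),
#'   `baseline_coeffs`, `corrected`, `residual_norm`, `scatter_score`
#'   (`||a||_2 / |b|`).
#' @examples
#' wn <- wavenumber_grid("QCL")
#' ref <- exp(-(wn - 1655)^2 / (2 * 12^2))
#' raw <- 2 * ref + 0.1 + 0.05 * (2 * (wn - min(wn)) / diff(range(wn)) - 1)
#' fit <- emsc_fit_correct(raw, ref, wn, poly_order = 1)
#' fit$b
#' @export
emsc_fit_correct <- function(spectrum, reference, wavenumbers,
                             poly_order = 2, extra_basis = NULL) {
  stopifnot(
    length(spectrum) == length(wavenumbers),
    length(reference) == length(wavenumbers),
    poly_order >= 0
  )
  fit <- emsc_fit_matrix(
    cbind(spectrum), reference, wavenumbers, poly_order, extra_basis
  )
  if (abs(fit$b[1]) <= 1e-8) {
    stop("degenerate EMSC fit: multiplicative coefficient ~ 0",
      call. = FALSE
    )
  }
  structure(
    list(
      b = fit$b[1],
      baseline_coeffs = drop(fit$baseline_coeffs),
      corrected = drop(fit$corrected),
      residual_norm = fit$residual_norm[1],
      scatter_score = fit$scatter_score[1],
      poly_order = poly_order
    ),
    class = "emsc_result"
  )
}

#' @export
print.emsc_result <- function(x, ...) {
  cat(
    "<emsc_result> b = ", signif(x$b, 4), ", ||a|| = ",
    signif(sqrt(sum(x$baseline_coeffs^2)), 4), ", residual norm = ",
    signif(x$residual_norm, 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Scatter-correct every pixel of an image
#'
#' Applies [emsc_fit_correct()] to all pixel spectra in one least-squares
#' solve. The default reference is the mean spectrum over valid pixels
#' (all pixels when no quality report is given).
#'
#' @param image A [spectral_image()].
#' @param reference Optional reference spectrum.
#' @param quality Optional [quality_filter()] report; invalid pixels are
#'   excluded from the default reference (they are still corrected).
#' @param poly_order Legendre baseline order.
#' @return List: `image` (corrected [spectral_image()]), `b` and
#'   `scatter_score` matrices, `reference`.
#' @export
emsc_correct_image <- function(image, reference = NULL, quality = NULL,
                               poly_order = 2) {
  stopifnot(inherits(image, "spectral_image"))
  Y <- t(as_spectra_matrix(image)) # n_wn x npix
  if (is.null(reference)) {
    use <- if (is.null(quality)) {
      rep(TRUE, ncol(Y))
    } else {
      as.vector(quality$valid)
    }
    if (!any(use)) use <- rep(TRUE, ncol(Y))
    reference <- rowMeans(Y[, use, drop = FALSE])
  }
  fit <- emsc_fit_matrix(Y, reference, image$wavenumbers, poly_order)
  d <- image_dim(image)
  corrected <- array(t(fit$corrected), c(d[1], d[2], length(image$wavenumbers)))
  list(
    image = spectral_image(corrected, image$wavenumbers, image$pixel_size,
      provenance = image$provenance
    ),
    b = matrix(fit$b, d[1], d[2]),
    scatter_score = matrix(fit$scatter_score, d[1], d[2]),
    reference = reference
  )
}
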