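#' Spectral band definition
#'
#' A band is quantified as a local-baseline-corrected peak height: the
#' maximum absorbance within `center +/- halfwidth` minus a straight
#' baseline through the mean absorbance of two flanking anchor windows.
#'
#' @param center Band center, 1/cm.
#' @param halfwidth Half-width of the measurement window, 1/cm.
#' @param anchor_left,anchor_right Length-2 wavenumber windows flanking the
#'   band (left = lower wavenumbers).
#' @return A `band_definition`.
#' @export
band_definition <- function(center, halfwidth, anchor_left, anchor_right) {
  stopifnot(
    halfwidth > 0,
    length(anchor_left) == 2, length(anchor_right) == 2,
    anchor_left[1] < anchor_left[2], anchor_right[1] < anchor_right[2]
  )
  if (anchor_left[2] > center - halfwidth ||
    anchor_right[1] < center + halfwidth) {
    stop("anchor windows must flank the measurement window", call. = FALSE)
  }
  structure(
    list(
      center = center, halfwidth = halfwidth,
      anchor_left = anchor_left, anchor_right = anchor_right
    ),
    class = "band_definition"
  )
}

#' Preset band definitions
#'
#' Defaults for the bands used across the workflow: the alkene =C-H
#' stretch at 3012 1/cm (unsaturation marker), the ester C=O stretch at
#' 1738 1/cm (total-lipid proxy), amide I at 1655 1/cm and its 1630 1/cm
#' beta-sheet shoulder (amyloid marker).
#'
#' @name band_presets
#' @return A `band_definition`.
#' @export
band_alkene <- function() {
  band_definition(3012, 15, c(2975, 2990), c(3035, 3050))
}

#' @rdname band_presets
#' @export
band_ester <- function() {
  band_definition(1738, 12, c(1700, 1712), c(1765, 1777))
}

#' @rdname band_presets
#' @export
band_amide1655 <- function() {
  band_definition(1655, 10, c(1580, 1596), c(1700, 1712))
}

#' @rdname band_presets
#' @export
band_amide1630 <- function() {
  band_definition(1630, 8, c(1580, 1596), c(1700, 1712))
}

band_indices <- function(wavenumbers, band) {
  win <- wavenumbers >= band$center - band$halfwidth &
    wavenumbers <= band$center + band$halfwidth
  left <- wavenumbers >= band$anchor_left[1] &
    wavenumbers <= band$anchor_left[2]
  right <- wavenumbers >= band$anchor_right[1] &
    wavenumbers <= band$anchor_right[2]
  if (!any(win) || !any(left) || !any(right)) {
    stop(
      "band at ", band$center,
      " 1/cm (or its anchors) outside the wavenumber grid",
      call. = FALSE
    )
  }
  list(win = which(win), left = which(left), right = which(right))
}

# vectorized band absorbance; Y is npix x n_wn
band_absorbance_matrix <- function(Y, wavenumbers, band,
                                   mode = c("height", "area")) {
  mode <- match.arg(mode)
  idx <- band_indices(wavenumbers, band)
  xl <- mean(wavenumbers[idx$left])
  xr <- mean(wavenumbers[idx$right])
  yl <- rowMeans(Y[, idx$left, drop = FALSE])
  yr <- rowMeans(Y[, idx$right, drop = FALSE])
  wx <- wavenumbers[idx$win]
  # baseline through (xl, yl) and (xr, yr), evaluated in the window
  frac <- (wx - xl) / (xr - xl)
  base <- outer(yl, rep(1, length(wx))) +
    outer(yr - yl, rep(1, length(wx))) * rep(frac, each = nrow(Y))
  net <- Y[, idx$win, drop = FALSE] - base
  if (mode == "height") {
    unname(pmax(apply(net, 1, max), 0))
  } else {
    widths <- diff(wx)
    trapz <- (net[, -1, drop = FALSE] + net[, -ncol(net), drop = FALSE]) / 2
    pmax(as.vector(trapz %*% widths), 0)
  }
}

#' Baseline-corrected band absorbance
#'
#' Peak height (default) or integrated area of a band above a local linear
#' baseline anchored in two flanking windows; floored at zero. Height is
#' invariant to adding any constant, and to any linear-in-wavenumber
#' function when the anchors are symmetric about the peak.
#'
#' @param spectrum Absorbance vector.
#' @param wavenumbers Wavenumber vector, 1/cm.
#' @param band A [band_definition()].
#' @param mode `"height"` or `"area"`.
#' @return Nonnegative scalar, AU (or AU * 1/cm for area).
#' @export
band_absorbance <- function(spectrum, wavenumbers, band,
                            mode = c("height", "area")) {
  stopifnot(length(spectrum) == length(wavenumbers))
  band_absorbance_matrix(rbind(spectrum), wavenumbers, band, mode)[1]
}

#' Lipid unsaturation index A3012/A1738
#'
#' Ratio of the alkene (=C-H, 3012 1/cm) to the ester carbonyl
#' (1738 1/cm) band absorbance: a per-spectrum measure of the degree of
#' unsaturation of the fatty acyl pool, independent of total lipid
#' content (the index is invariant to multiplicative scaling of the
#' spectrum).
#'
#' @param spectrum Absorbance vector.
#' @param wavenumbers Wavenumber vector; must cover the alkene band
#'   (full-range FTIR grids do, fingerprint-only QCL grids do not).
#' @param alkene_band,ester_band [band_definition()]s.
#' @param ester_floor Minimum ester absorbance (AU); below it the index is
#'   undefined (`NA`, essentially lipid-free pixel).
#' @param mode Band quantification mode.
#' @return Nonnegative scalar, or `NA` when the ester band is at floor.
#' @export
unsaturation_index <- function(spectrum, wavenumbers,
                               alkene_band = band_alkene(),
                               ester_band = band_ester(),
                               ester_floor = 1e-4,
                               mode = c("height", "area")) {
  if (max(wavenumbers) < alkene_band$center + alkene_band$halfwidth) {
    stop(
      "wavenumber grid does not cover the alkene band at ",
      alkene_band$center, " 1/cm (fingerprint-only acquisition?)",
      call. = FALSE
    )
  }
  alkene <- band_absorbance(spectrum, wavenumbers, alkene_band, mode)
  ester <- band_absorbance(spectrum, wavenumbers, ester_band, mode)
  if (ester <= ester_floor) {
    return(NA_real_)
  }
  alkene / ester
}

#' Per-pixel unsaturation map
#'
#' Applies [unsaturation_index()] to every valid pixel of an image;
#' pixels failing the quality filter (or with ester absorbance at floor)
#' are missing.
#'
#' @param image A [spectral_image()] on a full-range grid.
#' @param quality Optional [quality_filter()] report.
#' @param alkene_band,ester_band,ester_floor,mode As
#'   [unsaturation_index()].
#' @return An `unsaturation_map`: matrix `ratio` (NA = missing) plus the
#'   band definitions.
#' @export
unsaturation_map <- function(image, quality = NULL,
                             alkene_band = band_alkene(),
                             ester_band = band_ester(),
                             ester_floor = 1e-4,
                             mode = c("height", "area")) {
  stopifnot(inherits(image, "spectral_image"))
  wn <- image$wavenumbers
  if (max(wn) < alkene_band$center + alkene_band$halfwidth) {
    stop(
      "wavenumber grid does not cover the alkene band at ",
      alkene_band$center, " 1/cm",
      call. = FALSE
    )
  }
  Y <- as_spectra_matrix(image)
  alkene <- band_absorbance_matrix(Y, wn, alkene_band, mode)
  ester <- band_absorbance_matrix(Y, wn, ester_band, mode)
  ratio <- ifelse(ester > ester_floor, alkene / ester, NA_real_)
  if (!is.null(quality)) ratio[!as.vector(quality$valid)] <- NA_real_
  d <- image_dim(image)
  structure(
    list(
      ratio = matrix(ratio, d[1], d[2]),
      alkene_band = alkene_band, ester_band = ester_band,
      pixel_size = image$pixel_size
    ),
    class = "unsaturation_map"
  )
}

#' @export
print.unsaturation_map <- function(x, ...) {
  cat(
    "<unsaturation_map> ", nrow(x$ratio), "x", ncol(x$ratio),
    " px; A", x$alkene_band$center, "/A", x$ester_band$center,
    "; mean = ", signif(mean(x$ratio, na.rm = TRUE), 4),
    " (", sum(is.na(x$ratio)), " missing)\n",
    sep = ""
  )
  invisible(x)
}
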