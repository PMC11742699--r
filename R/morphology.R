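#' Morphological refinement parameters
#'
#' The sequential cascade applied to binarized activation masks before
#' laser microdissection: tiny objects are discarded, the mask is dilated
#' (adding a safety margin and merging fragments), holes are filled, the
#' mask is eroded back (net margin = dilate - erode, default +5 um to
#' absorb tissue loss in later processing), small objects are discarded
#' again, and elongated or ragged objects are removed by eccentricity and
#' solidity criteria.
#'
#' @param binarize_threshold Activation threshold in (0, 1).
#' @param min_area_pre Minimum object area before dilation, um^2.
#' @param dilate_radius,erode_radius Disc radii, um (rounded to >= 1 px).
#' @param min_area_post Minimum object area after erosion, um^2.
#' @param max_eccentricity,min_solidity Shape criteria (the source
#'   protocol leaves the cutoffs unspecified; these defaults keep
#'   approximately round, compact objects and are logged with results).
#' @return A `morph_params` list.
#' @export
morph_params <- function(binarize_threshold = 0.9,
                         min_area_pre = 100,
                         dilate_radius = 15,
                         erode_radius = 10,
                         min_area_post = 300,
                         max_eccentricity = 0.95,
                         min_solidity = 0.7) {
  stopifnot(
    binarize_threshold > 0, binarize_threshold < 1,
    min_area_pre >= 0, min_area_post >= 0,
    dilate_radius >= 0, erode_radius >= 0,
    dilate_radius - erode_radius >= 0,
    max_eccentricity >= 0, max_eccentricity <= 1,
    min_solidity > 0, min_solidity <= 1
  )
  structure(
    list(
      binarize_threshold = binarize_threshold,
      min_area_pre = min_area_pre,
      dilate_radius = dilate_radius,
      erode_radius = erode_radius,
      min_area_post = min_area_post,
      max_eccentricity = max_eccentricity,
      min_solidity = min_solidity
    ),
    class = "morph_params"
  )
}

label_components <- function(mask) {
  EBImage::bwlabel(EBImage::Image(mask * 1))
}

remove_small <- function(labels, min_area_px) {
  counts <- table(labels[labels > 0])
  drop <- as.integer(names(counts)[counts < min_area_px])
  m <- as.matrix(labels)
  m[m %in% drop] <- 0L
  m > 0
}

#' Shape metrics of a connected component
#'
#' Area (pixel count times pixel area), eccentricity from the ellipse of
#' the second central moments of the pixel centers, and solidity as the
#' pixel count divided by the pixel count of the discrete convex hull
#' (pixels whose centers fall inside or on the hull of the component's
#' pixel corners).
#'
#' @param pixels Two-column matrix of (row, col) pixel indices of one
#'   component.
#' @param pixel_size Pixel edge, um.
#' @return One-row tibble with `area_um2`, `eccentricity`, `solidity`.
#' @export
shape_metrics <- function(pixels, pixel_size = 1) {
  pixels <- as.matrix(pixels)
  stopifnot(ncol(pixels) == 2, nrow(pixels) >= 1)
  n <- nrow(pixels)
  area <- n * pixel_size^2
  if (n == 1) {
    return(tibble::tibble(area_um2 = area, eccentricity = 0, solidity = 1))
  }
  ctr <- colMeans(pixels)
  dx <- pixels[, 1] - ctr[1]
  dy <- pixels[, 2] - ctr[2]
  cov <- matrix(c(mean(dx^2), mean(dx * dy), mean(dx * dy), mean(dy^2)), 2)
  ev <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values,
    decreasing = TRUE
  )
  ecc <- if (ev[1] <= 0) 0 else sqrt(max(0, 1 - ev[2] / ev[1]))

  # discrete convex hull: corners of every pixel, then count pixel centers
  # inside (or on) the hull polygon
  corners <- rbind(
    cbind(pixels[, 1] - 0.5, pixels[, 2] - 0.5),
    cbind(pixels[, 1] - 0.5, pixels[, 2] + 0.5),
    cbind(pixels[, 1] + 0.5, pixels[, 2] - 0.5),
    cbind(pixels[, 1] + 0.5, pixels[, 2] + 0.5)
  )
  h <- grDevices::chull(corners)
  hx <- corners[h, 1]
  hy <- corners[h, 2]
  rr <- seq(min(pixels[, 1]), max(pixels[, 1]))
  cc <- seq(min(pixels[, 2]), max(pixels[, 2]))
  grid <- cbind(rep(rr, length(cc)), rep(cc, each = length(rr)))
  inside <- pracma::inpolygon(grid[, 1], grid[, 2], hx, hy,
    boundary = TRUE
  )
  solidity <- n / sum(inside)
  tibble::tibble(area_um2 = area, eccentricity = ecc, solidity = solidity)
}

#' Morphological refinement of a plaque mask
#'
#' Applies, in order: removal of components below `min_area_pre`;
#' dilation by a disc of `dilate_radius`; hole filling; erosion by a disc
#' of `erode_radius`; removal of components below `min_area_post`; and
#' removal of components failing the eccentricity or solidity criteria.
#' Metric radii are converted to pixels by rounding (at least 1 px).
#'
#' @param mask Logical matrix (binarized activation).
#' @param pixel_size Pixel edge, um.
#' @param params A [morph_params()].
#' @return Refined logical mask (empty in, empty out).
#' @export
morphological_refine <- function(mask, pixel_size, params = morph_params()) {
  stopifnot(pixel_size > 0, inherits(params, "morph_params"))
  if (!any(mask)) {
    return(mask & FALSE)
  }
  px_area <- pixel_size^2
  m <- remove_small(label_components(mask), params$min_area_pre / px_area)
  if (any(m) && params$dilate_radius > 0) {
    m <- as.matrix(EBImage::dilate(
      EBImage::Image(m * 1), disc_brush(params$dilate_radius / pixel_size)
    )) > 0.5
  }
  if (any(m)) {
    m <- as.matrix(EBImage::fillHull(EBImage::Image(m * 1))) > 0.5
  }
  if (any(m) && params$erode_radius > 0) {
    m <- as.matrix(EBImage::erode(
      EBImage::Image(m * 1), disc_brush(params$erode_radius / pixel_size)
    )) > 0.5
  }
  if (any(m)) {
    m <- remove_small(label_components(m), params$min_area_post / px_area)
  }
  if (any(m)) {
    labels <- label_components(m)
    lm <- as.matrix(labels)
    for (k in seq_len(max(lm))) {
      px <- which(lm == k, arr.ind = TRUE)
      if (nrow(px) == 0) next
      met <- shape_metrics(px, pixel_size)
      if (met$eccentricity > params$max_eccentricity ||
        met$solidity < params$min_solidity) {
        m[px] <- FALSE
      }
    }
  }
  m
}
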