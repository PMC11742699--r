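#' Tile anchors along one dimension
#'
#' Tiles of size `tile_size` advance with stride `tile_size - overlap`;
#' the final tile is anchored flush to the edge (extra overlap instead of
#' padding), so the union of tiles always covers `[1, n]`.
#'
#' @param n Extent in pixels.
#' @param tile_size Tile edge, pixels.
#' @param overlap Overlap between successive tiles, pixels
#'   (`0 <= overlap < tile_size`).
#' @return Integer vector of 1-based tile start positions.
#' @export
tile_anchors <- function(n, tile_size = 64L, overlap = 16L) {
  stopifnot(overlap >= 0, overlap < tile_size)
  if (n < tile_size) {
    stop("image extent (", n, ") smaller than the tile size (", tile_size,
      ")",
      call. = FALSE
    )
  }
  stride <- tile_size - overlap
  anchors <- seq(1L, n - tile_size + 1L, by = stride)
  if (anchors[length(anchors)] + tile_size - 1L < n) {
    anchors <- c(anchors, n - tile_size + 1L)
  }
  as.integer(anchors)
}

#' Cut a whole-slide image into overlapping tiles
#'
#' @param image A [spectral_image()] (whole-slide QCL acquisition).
#' @param tile_size,overlap Tiling geometry (defaults 64 px with 16 px
#'   overlap).
#' @return A list of tiles, each `list(row, col, image)` where `row`/`col`
#'   are the 1-based anchor coordinates of the tile's top-left pixel.
#' @export
tile_wsi <- function(image, tile_size = 64L, overlap = 16L) {
  stopifnot(inherits(image, "spectral_image"))
  d <- image_dim(image)
  rows <- tile_anchors(d[1], tile_size, overlap)
  cols <- tile_anchors(d[2], tile_size, overlap)
  tiles <- list()
  for (r in rows) {
    for (cc in cols) {
      sub <- image$absorbance[
        r:(r + tile_size - 1L), cc:(cc + tile_size - 1L), ,
        drop = FALSE
      ]
      tiles[[length(tiles) + 1L]] <- list(
        row = r, col = cc,
        image = spectral_image(sub, image$wavenumbers, image$pixel_size,
          provenance = image$provenance
        )
      )
    }
  }
  tiles
}

#' Score tiles with a pluggable per-pixel scorer
#'
#' Each tile is evaluated independently by `scorer`, a function taking a
#' tile [spectral_image()] and returning a matrix of per-pixel plaque
#' scores in `[0, 1]` of the tile's pixel dimensions. The trained
#' segmentation network of the original workflow is one such scorer; the
#' package ships [amide_shift_scorer()] as a fully specified spectral
#' reference scorer so the chain is exercisable end to end.
#'
#' @param tiles Result of [tile_wsi()].
#' @param scorer `function(tile_image) -> matrix` of scores in `[0, 1]`.
#' @return The tiles with an added `scores` matrix each.
#' @export
score_tiles <- function(tiles, scorer) {
  stopifnot(is.function(scorer))
  lapply(tiles, function(tl) {
    s <- scorer(tl$image)
    d <- image_dim(tl$image)
    if (!is.matrix(s) || !all(dim(s) == d)) {
      stop("scorer must return a ", d[1], "x", d[2], " matrix",
        call. = FALSE
      )
    }
    if (any(!is.finite(s)) || any(s < 0 | s > 1)) {
      stop("scorer returned scores outside [0, 1]", call. = FALSE)
    }
    tl$scores <- s
    tl
  })
}

#' Reassemble tile scores into a whole-slide activation map
#'
#' Every whole-slide pixel receives the maximum score over all tiles that
#' contain it, preserving detections across tile seams.
#'
#' @param scored_tiles Result of [score_tiles()].
#' @param image_shape `c(rows, cols)` of the whole-slide image.
#' @return An `activation_map`: matrix `scores` in `[0, 1]`.
#' @export
assemble_activation <- function(scored_tiles, image_shape) {
  acc <- matrix(-Inf, image_shape[1], image_shape[2])
  for (tl in scored_tiles) {
    if (is.null(tl$scores)) stop("tiles are not scored", call. = FALSE)
    d <- dim(tl$scores)
    ri <- tl$row:(tl$row + d[1] - 1L)
    ci <- tl$col:(tl$col + d[2] - 1L)
    if (max(ri) > image_shape[1] || max(ci) > image_shape[2]) {
      stop("tile extends beyond the image", call. = FALSE)
    }
    acc[ri, ci] <- pmax(acc[ri, ci], tl$scores)
  }
  if (any(!is.finite(acc))) {
    stop("tiles do not cover the image: ", sum(!is.finite(acc)),
      " uncovered pixel(s)",
      call. = FALSE
    )
  }
  structure(
    list(scores = acc),
    class = "activation_map"
  )
}

#' @export
print.activation_map <- function(x, ...) {
  cat(
    "<activation_map> ", nrow(x$scores), "x", ncol(x$scores),
    " px; score range ", signif(min(x$scores), 3), "-",
    signif(max(x$scores), 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' Binarize an activation map
#'
#' @param map An `activation_map` (or plain score matrix).
#' @param threshold Score threshold within `[0, 1]` (default 0.9).
#' @return Logical plaque mask (`scores >= threshold`).
#' @export
binarize_activation <- function(map, threshold = 0.9) {
  s <- if (inherits(map, "activation_map")) map$scores else map
  s >= threshold
}

#' Reference spectral-contrast scorer: amide I shift
#'
#' Amyloid deposits are beta-sheet rich, which shifts amide I intensity
#' from ~1655 1/cm towards ~1630 1/cm. This scorer computes the per-pixel
#' baseline-corrected absorbance ratio A1630/A1655 and squashes it through
#' a fixed linear ramp: scores are 0 at `lo` and below, 1 at `hi` and
#' above. The ramp endpoints are package defaults matched to the
#' synthetic band model (background ratio vs. lesions with an elevated
#' 1630 shoulder); they are deliberately fixed constants, not
#' data-dependent min-max, so scores are comparable across tiles.
#'
#' @param lo,hi Ramp endpoints on the A1630/A1655 ratio scale.
#' @param amide1630,amide1655 [band_definition()]s.
#' @return A scorer `function(tile_image) -> matrix` for [score_tiles()].
#' @export
amide_shift_scorer <- function(lo = 0.58, hi = 0.63,
                               amide1630 = band_amide1630(),
                               amide1655 = band_amide1655()) {
  stopifnot(hi > lo)
  function(tile_image) {
    Y <- as_spectra_matrix(tile_image)
    wn <- tile_image$wavenumbers
    a30 <- band_absorbance_matrix(Y, wn, amide1630)
    a55 <- band_absorbance_matrix(Y, wn, amide1655)
    r <- ifelse(a55 > 1e-6, a30 / a55, 0)
    d <- image_dim(tile_image)
    matrix(pmin(1, pmax(0, (r - lo) / (hi - lo))), d[1], d[2])
  }
}

#' Pixel-level detection metrics
#'
#' Precision, recall and F1 of a predicted plaque mask against the
#' ground-truth lesion mask.
#'
#' @param predicted,truth Logical matrices of equal size.
#' @return One-row tibble with `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`.
#' @export
detection_metrics <- function(predicted, truth) {
  stopifnot(all(dim(predicted) == dim(truth)))
  tp <- sum(predicted & truth)
  fp <- sum(predicted & !truth)
  fn <- sum(!predicted & truth)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    precision = precision, recall = recall, f1 = f1
  )
}
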