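#' Point-pair sets for image registration
#'
#' User-provided reference coordinates linking two images: `sx, sy` in the
#' source image and `tx, ty` in the target image (pixels or micrometres,
#' as long as both sides are consistent).
#'
#' @param source,target Two-column matrices/data frames of (x, y)
#'   coordinates, equal row counts.
#' @return A tibble with columns `sx`, `sy`, `tx`, `ty`.
#' @export
point_pairs <- function(source, target) {
  source <- as.matrix(source)
  target <- as.matrix(target)
  stopifnot(ncol(source) == 2, ncol(target) == 2,
    nrow(source) == nrow(target))
  tibble::tibble(
    sx = source[, 1], sy = source[, 2],
    tx = target[, 1], ty = target[, 2]
  )
}

#' @rdname point_pairs
#' @param path CSV path with columns `sx, sy, tx, ty`.
#' @export
read_point_pairs <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()))
}

#' @rdname point_pairs
#' @param pairs A point-pair tibble.
#' @export
write_point_pairs <- function(pairs, path) {
  stopifnot(all(c("sx", "sy", "tx", "ty") %in% names(pairs)))
  readr::write_csv(pairs[, c("sx", "sy", "tx", "ty")], path)
  invisible(path)
}

new_transform2d <- function(A, t, class, extra = list()) {
  structure(
    c(list(A = A, t = as.numeric(t)), extra),
    class = c(class, "transform2d")
  )
}

#' Fit an affine 2-D transform from point pairs
#'
#' Least-squares estimate of `target ~ A %*% source + t` (6 parameters),
#' used to bring immunofluorescence images into the vibrational image's
#' coordinate system. Exact for 3 non-collinear pairs.
#'
#' @param pairs Point pairs (see [point_pairs()]), at least 3 and not
#'   collinear.
#' @return An `affine_transform2d` (also `transform2d`) with `A` (2x2),
#'   `t` (length 2) and `residual_rms` for registration quality control.
#' @export
fit_affine_transform <- function(pairs) {
  stopifnot(all(c("sx", "sy", "tx", "ty") %in% names(pairs)))
  n <- nrow(pairs)
  if (n < 3) stop("need at least 3 point pairs for an affine fit",
    call. = FALSE)
  X <- cbind(pairs$sx, pairs$sy, 1)
  if (qr(X)$rank < 3) {
    stop("degenerate geometry: source points are collinear", call. = FALSE)
  }
  cx <- qr.coef(qr(X), pairs$tx)
  cy <- qr.coef(qr(X), pairs$ty)
  A <- rbind(cx[1:2], cy[1:2])
  t <- c(cx[3], cy[3])
  if (abs(det(A)) <= 1e-12) {
    stop("degenerate affine transform (singular linear part)", call. = FALSE)
  }
  pred <- cbind(pairs$sx, pairs$sy) %*% t(A) +
    matrix(t, n, 2, byrow = TRUE)
  rms <- sqrt(mean((pred - cbind(pairs$tx, pairs$ty))^2))
  new_transform2d(A, t, "affine_transform2d",
    list(residual_rms = rms, n_pairs = n))
}

#' Fit a 2-D Helmert (similarity) transform from point pairs
#'
#' Least-squares 4-parameter conformal transform (uniform scale, rotation,
#' translation; no shear), used to map refined plaque shapes from image to
#' microscope stage coordinates. Exact for 2 distinct pairs. Writing
#' `p = s cos(theta)`, `q = s sin(theta)`, the model
#' `tx = p sx - q sy + t1; ty = q sx + p sy + t2` is linear in
#' `(p, q, t1, t2)` and solved by ordinary least squares.
#'
#' @param pairs Point pairs, at least 2, source points not all coincident.
#' @return A `helmert_transform2d` (also `transform2d`) with `A`, `t`,
#'   `scale`, `rotation` (radians) and `residual_rms`.
#' @export
fit_helmert_transform <- function(pairs) {
  stopifnot(all(c("sx", "sy", "tx", "ty") %in% names(pairs)))
  n <- nrow(pairs)
  if (n < 2) stop("need at least 2 point pairs for a Helmert fit",
    call. = FALSE)
  if (stats::sd(pairs$sx) == 0 && stats::sd(pairs$sy) == 0) {
    stop("degenerate geometry: source points are coincident", call. = FALSE)
  }
  X <- rbind(
    cbind(pairs$sx, -pairs$sy, 1, 0),
    cbind(pairs$sy, pairs$sx, 0, 1)
  )
  y <- c(pairs$tx, pairs$ty)
  beta <- qr.coef(qr(X), y)
  p <- beta[1]
  q <- beta[2]
  s <- sqrt(p^2 + q^2)
  if (s <= 1e-12) stop("degenerate Helmert fit: zero scale", call. = FALSE)
  A <- rbind(c(p, -q), c(q, p))
  t <- beta[3:4]
  pred <- cbind(pairs$sx, pairs$sy) %*% t(A) + matrix(t, n, 2, byrow = TRUE)
  rms <- sqrt(mean((pred - cbind(pairs$tx, pairs$ty))^2))
  new_transform2d(A, t, "helmert_transform2d", list(
    scale = s, rotation = atan2(q, p), residual_rms = rms, n_pairs = n
  ))
}

#' Apply or invert a 2-D transform
#'
#' @param transform A `transform2d` (affine or Helmert).
#' @param points Two-column matrix/data frame of (x, y).
#' @return Matrix of transformed coordinates.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "transform2d"))
  pts <- as.matrix(points)
  if (is.null(dim(pts)) || ncol(pts) != 2) {
    pts <- matrix(pts, ncol = 2, byrow = TRUE)
  }
  out <- pts %*% t(transform$A) +
    matrix(transform$t, nrow(pts), 2, byrow = TRUE)
  colnames(out) <- c("x", "y")
  out
}

#' @rdname apply_transform
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "transform2d"))
  Ainv <- solve(transform$A)
  extra <- list()
  cls <- "affine_transform2d"
  if (inherits(transform, "helmert_transform2d")) {
    cls <- "helmert_transform2d"
    extra <- list(
      scale = 1 / transform$scale,
      rotation = -transform$rotation
    )
  }
  new_transform2d(Ainv, -Ainv %*% transform$t, cls, extra)
}

#' @export
print.transform2d <- function(x, ...) {
  kind <- if (inherits(x, "helmert_transform2d")) "helmert" else "affine"
  cat("<", kind, "_transform2d> t = (", paste(signif(x$t, 6),
    collapse = ", "), ")\n", sep = "")
  if (!is.null(x$scale)) {
    cat("  scale = ", signif(x$scale, 6), ", rotation = ",
      signif(x$rotation * 180 / pi, 6), " deg\n", sep = "")
  }
  print(signif(x$A, 6))
  if (!is.null(x$residual_rms)) {
    cat("  residual RMS = ", signif(x$residual_rms, 4), " (", x$n_pairs,
      " pairs)\n", sep = "")
  }
  invisible(x)
}

#' Transform JSON serialization
#'
#' @param transform A `transform2d`.
#' @param path JSON file path.
#' @return `write_transform_json()` returns `path` invisibly;
#'   `read_transform_json()` the restored transform.
#' @export
write_transform_json <- function(transform, path) {
  stopifnot(inherits(transform, "transform2d"))
  jsonlite::write_json(
    list(
      kind = if (inherits(transform, "helmert_transform2d")) {
        "helmert"
      } else {
        "affine"
      },
      matrix = transform$A,
      translation = transform$t
    ),
    path,
    digits = NA
  )
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  A <- matrix(unlist(obj$matrix), 2, 2)
  t <- as.numeric(obj$translation)
  if (identical(obj$kind[1], "helmert")) {
    new_transform2d(A, t, "helmert_transform2d", list(
      scale = sqrt(A[1, 1]^2 + A[2, 1]^2),
      rotation = atan2(A[2, 1], A[1, 1])
    ))
  } else {
    new_transform2d(A, t, "affine_transform2d")
  }
}
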