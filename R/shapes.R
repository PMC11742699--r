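shoelace_area <- function(xy) {
  x <- xy[, 1]
  y <- xy[, 2]
  n <- nrow(xy)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Extract LMD-ready polygons from a refined plaque mask
#'
#' Traces the outer boundary of every connected component at the
#' half-pixel iso-contour: a filled rectangle of `n` pixels yields a
#' polygon of `n` pixel areas up to a 0.125 px^2 chamfer per convex
#' corner (the contour cuts corners diagonally). It converts pixel
#' coordinates to
#' micrometres (pixel centers at `(i - 0.5) * pixel_size`, x = columns,
#' y = rows, origin top-left), and applies an optional Helmert transform
#' into microscope stage coordinates. Components touching the image
#' border are excluded with a warning (their outline is not closed on
#' tissue).
#'
#' @param mask Logical matrix (refined plaque mask).
#' @param pixel_size Pixel edge, um.
#' @param transform Optional `transform2d` (image um -> stage um);
#'   `NULL` keeps image coordinates.
#' @param min_area_um2 Minimum polygon area kept, um^2.
#' @return A `shape_set`: tibble with `object_id`, `area_um2` and a
#'   `polygon` list-column of closed (first row = last row) two-column
#'   matrices in target coordinates.
#' @export
shapes_from_mask <- function(mask, pixel_size, transform = NULL,
                             min_area_um2 = 0) {
  stopifnot(is.matrix(mask), pixel_size > 0)
  labels <- as.matrix(label_components(mask))
  n_comp <- max(labels)
  polys <- list()
  areas <- numeric(0)
  ids <- integer(0)
  dropped_border <- 0L
  for (k in seq_len(n_comp)) {
    px <- which(labels == k, arr.ind = TRUE)
    if (any(px[, 1] == 1 | px[, 1] == nrow(mask) |
      px[, 2] == 1 | px[, 2] == ncol(mask))) {
      dropped_border <- dropped_border + 1L
      next
    }
    comp <- labels == k
    # pad so the iso-contour closes; coordinates of pixel centers in um,
    # first contour axis = rows (y), second = columns (x)
    padded <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
    padded[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- comp * 1
    yc <- ((0:(nrow(mask) + 1)) - 0.5) * pixel_size
    xc <- ((0:(ncol(mask) + 1)) - 0.5) * pixel_size
    cl <- grDevices::contourLines(x = yc, y = xc, z = padded, levels = 0.5)
    if (length(cl) == 0) next
    # keep the longest ring (outer boundary; holes were filled upstream)
    ring <- cl[[which.max(vapply(cl, function(r) length(r$x), numeric(1)))]]
    xy <- cbind(x = ring$y, y = ring$x) # contour x was rows -> map to y
    if (nrow(xy) < 4) next
    if (any(xy[1, ] != xy[nrow(xy), ])) xy <- rbind(xy, xy[1, ])
    if (!is.null(transform)) {
      txy <- apply_transform(transform, xy)
      xy <- cbind(x = txy[, 1], y = txy[, 2])
    }
    a <- shoelace_area(xy[-nrow(xy), , drop = FALSE])
    if (a < min_area_um2) next
    polys[[length(polys) + 1]] <- xy
    areas <- c(areas, a)
    ids <- c(ids, k)
  }
  if (dropped_border > 0) {
    warning(dropped_border, " component(s) touching the image border excluded",
      call. = FALSE
    )
  }
  structure(
    tibble::tibble(object_id = ids, area_um2 = areas, polygon = polys),
    class = c("shape_set", "tbl_df", "tbl", "data.frame")
  )
}

#' @export
print.shape_set <- function(x, ...) {
  cat(
    "<shape_set> ", nrow(x), " polygon(s), total area ",
    signif(sum(x$area_um2), 6), " um^2\n",
    sep = ""
  )
  NextMethod()
}

polygon_to_wkt <- function(xy, digits = 10) {
  coords <- apply(xy, 1, function(p) {
    paste(format(p[1], digits = digits, scientific = FALSE, trim = TRUE),
      format(p[2], digits = digits, scientific = FALSE, trim = TRUE))
  })
  paste0("POLYGON ((", paste(coords, collapse = ", "), "))")
}

wkt_to_polygon <- function(wkt) {
  inner <- sub("^POLYGON \\(\\(", "", sub("\\)\\)$", "", wkt))
  pts <- strsplit(strsplit(inner, ", ")[[1]], " ")
  xy <- do.call(rbind, lapply(pts, as.numeric))
  colnames(xy) <- c("x", "y")
  xy
}

#' Export / import LMD shape sets
#'
#' Writes polygons in stage coordinates for downstream laser
#' microdissection either as a WKT-polygon CSV (`id, area_um2, wkt`) or as
#' GeoJSON (`FeatureCollection` of polygons with `id` and `area_um2`
#' properties). Read-back round-trips coordinates to better than 1e-6 um.
#'
#' @param shapes A `shape_set` from [shapes_from_mask()].
#' @param path Output file path.
#' @param format `"wkt_csv"` or `"geojson"`.
#' @return `export_shapes()` returns `path` invisibly; `read_shapes()` the
#'   restored `shape_set`.
#' @export
export_shapes <- function(shapes, path, format = c("wkt_csv", "geojson")) {
  format <- match.arg(format)
  if (format == "wkt_csv") {
    tbl <- tibble::tibble(
      id = shapes$object_id,
      area_um2 = shapes$area_um2,
      wkt = vapply(shapes$polygon, polygon_to_wkt, character(1))
    )
    readr::write_csv(tbl, path)
  } else {
    features <- purrr::map2(
      shapes$polygon, seq_len(nrow(shapes)),
      function(xy, i) {
        list(
          type = "Feature",
          properties = list(
            id = shapes$object_id[i],
            area_um2 = shapes$area_um2[i]
          ),
          geometry = list(
            type = "Polygon",
            coordinates = list(unname(apply(xy, 1, c, simplify = FALSE)))
          )
        )
      }
    )
    jsonlite::write_json(
      list(type = "FeatureCollection", features = features),
      path,
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' @rdname export_shapes
#' @export
read_shapes <- function(path, format = c("wkt_csv", "geojson")) {
  format <- match.arg(format)
  if (format == "wkt_csv") {
    tbl <- readr::read_csv(path, col_types = "idc")
    polys <- lapply(tbl$wkt, wkt_to_polygon)
    out <- tibble::tibble(
      object_id = tbl$id, area_um2 = tbl$area_um2, polygon = polys
    )
  } else {
    obj <- jsonlite::read_json(path)
    out <- tibble::tibble(
      object_id = vapply(obj$features, function(f) {
        as.integer(f$properties$id)
      }, integer(1)),
      area_um2 = vapply(obj$features, function(f) {
        as.numeric(f$properties$area_um2)
      }, numeric(1)),
      polygon = lapply(obj$features, function(f) {
        xy <- do.call(rbind, lapply(
          f$geometry$coordinates[[1]],
          function(p) as.numeric(unlist(p))
        ))
        colnames(xy) <- c("x", "y")
        xy
      })
    )
  }
  structure(out, class = c("shape_set", "tbl_df", "tbl", "data.frame"))
}
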