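#' Default vibrational band table
#'
#' Gaussian band model for grey-matter tissue spectra: C-H stretches (2850,
#' 2920, 2960), the alkene =C-H stretch of unsaturated acyl chains (3012),
#' the ester carbonyl of glycerolipids (1738), amide I (1655) with its
#' beta-sheet shoulder (1630, elevated in amyloid deposits), and amide II
#' (1545). `width` is the Gaussian sigma; `amplitude` the peak height above
#' zero baseline, absorbance units.
#'
#' @return Tibble with columns `center`, `width`, `amplitude`.
#' @export
default_band_table <- function() {
  tibble::tribble(
    ~center, ~width, ~amplitude,
    2850, 9, 0.25,
    2920, 10, 0.35,
    2956, 7, 0.15,
    3012, 8, 0.05,
    1738, 8, 0.20,
    1655, 12, 0.40,
    1630, 10, 0.12,
    1545, 12, 0.25
  )
}

#' Configuration of a synthetic IR scene
#'
#' Describes an additive-band hyperspectral scene: a homogeneous tissue
#' background built from Gaussian vibrational bands, circular plaque
#' lesions in which the alkene band is depressed (`alkene_scale` < 1,
#' emulating unsaturated-lipid loss) and the 1630 amide shoulder elevated
#' (`amide1630_scale` > 1, emulating beta-sheet amyloid), a smooth
#' sinusoid-plus-slope baseline standing in for Mie scatter ripple, and
#' i.i.d. Gaussian noise.
#'
#' @param grid `"FTIR"` (3700-948 1/cm, 1.9 1/cm sampling, 1.1 um pixels)
#'   or `"QCL"` (1800-948 1/cm, 2 1/cm sampling, 4.25 um pixels).
#' @param image_shape Pixels, `c(rows, cols)`. Defaults: 128 x 128 (FTIR
#'   detector tile), 480 x 480 (QCL field of view).
#' @param pixel_size Micrometres per pixel (grid default if `NULL`).
#' @param band_table Tibble as [default_band_table()].
#' @param plaque_lesions Tibble with columns `row`, `col` (lesion center,
#'   pixels), `radius_um`, `alkene_scale` in (0, 1], `amide1630_scale`
#'   >= 1.
#' @param scatter_amplitude Peak amplitude (AU) of the per-pixel baseline
#'   ripple; 0 disables.
#' @param scatter_map Optional matrix of per-pixel multipliers on
#'   `scatter_amplitude`.
#' @param noise_sd SD of additive Gaussian noise, AU.
#' @param seed Integer seed.
#' @return An `ir_scene_config` object.
#' @export
ir_scene_config <- function(grid = c("FTIR", "QCL"),
                            image_shape = NULL,
                            pixel_size = NULL,
                            band_table = default_band_table(),
                            plaque_lesions = NULL,
                            scatter_amplitude = 0,
                            scatter_map = NULL,
                            noise_sd = 0,
                            seed = 20260101L) {
  grid <- match.arg(grid)
  if (is.null(image_shape)) {
    image_shape <- if (grid == "FTIR") c(128L, 128L) else c(480L, 480L)
  }
  if (is.null(pixel_size)) {
    pixel_size <- if (grid == "FTIR") 1.1 else 4.25
  }
  if (is.null(plaque_lesions)) {
    plaque_lesions <- tibble::tibble(
      row = numeric(0), col = numeric(0), radius_um = numeric(0),
      alkene_scale = numeric(0), amide1630_scale = numeric(0)
    )
  }
  stopifnot(
    length(image_shape) == 2, all(image_shape >= 1),
    pixel_size > 0, noise_sd >= 0, scatter_amplitude >= 0,
    all(c("center", "width", "amplitude") %in% names(band_table)),
    all(c("row", "col", "radius_um", "alkene_scale", "amide1630_scale")
    %in% names(plaque_lesions))
  )
  if (nrow(plaque_lesions) > 0) {
    stopifnot(
      all(plaque_lesions$radius_um > 0),
      all(plaque_lesions$alkene_scale > 0 & plaque_lesions$alkene_scale <= 1),
      all(plaque_lesions$amide1630_scale >= 1)
    )
  }
  structure(
    list(
      grid = grid, image_shape = as.integer(image_shape),
      pixel_size = pixel_size, band_table = band_table,
      plaque_lesions = plaque_lesions,
      scatter_amplitude = scatter_amplitude, scatter_map = scatter_map,
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "ir_scene_config"
  )
}

#' Wavenumber grid of an acquisition mode
#'
#' @param grid `"FTIR"` or `"QCL"`.
#' @return Ascending wavenumber vector: 948-3699.2 1/cm in 1.9 1/cm steps
#'   (FTIR) or 948-1800 1/cm in 2 1/cm steps (QCL).
#' @export
wavenumber_grid <- function(grid = c("FTIR", "QCL")) {
  grid <- match.arg(grid)
  if (grid == "FTIR") seq(948, 3700, by = 1.9) else seq(948, 1800, by = 2)
}

#' Generate a synthetic IR hyperspectral scene
#'
#' Builds the scene described by an [ir_scene_config()] and returns both
#' the cube and pixel-true ground truth, so detection and band-ratio
#' stages can be scored against a known answer. Inside a lesion the alkene
#' (3012 1/cm) band amplitude is multiplied by `alkene_scale` and the
#' 1630 1/cm amide shoulder by `amide1630_scale`; at zero noise the
#' lesion-to-background ratio of baseline-corrected A3012/A1738 therefore
#' equals `alkene_scale` by construction.
#'
#' @param config An [ir_scene_config()].
#' @return List with `image` (a [spectral_image()]), `plaque_mask` (logical
#'   matrix, TRUE inside lesions) and `lesion_id` (integer matrix, 0 =
#'   background).
#' @export
generate_ir_scene <- function(config = ir_scene_config()) {
  stopifnot(inherits(config, "ir_scene_config"))
  wn <- wavenumber_grid(config$grid)
  nr <- config$image_shape[1]
  nc <- config$image_shape[2]
  npix <- nr * nc
  bands <- config$band_table

  lesions <- config$plaque_lesions
  if (nrow(lesions) > 0 &&
    (any(lesions$row < 1 | lesions$row > nr) ||
      any(lesions$col < 1 | lesions$col > nc))) {
    stop("lesion center outside the image", call. = FALSE)
  }

  # Gaussian band profiles on the grid: n_wn x n_bands
  profiles <- vapply(seq_len(nrow(bands)), function(i) {
    exp(-(wn - bands$center[i])^2 / (2 * bands$width[i]^2))
  }, numeric(length(wn)))

  # per-pixel band amplitudes
  amp <- matrix(rep(bands$amplitude, each = npix), npix, nrow(bands))
  lesion_id <- matrix(0L, nr, nc)
  if (nrow(lesions) > 0) {
    ctr_r <- (seq_len(nr) - 0.5) * config$pixel_size
    ctr_c <- (seq_len(nc) - 0.5) * config$pixel_size
    alkene_col <- which(bands$center == 3012)
    amide_col <- which(bands$center == 1630)
    for (k in seq_len(nrow(lesions))) {
      cr <- (lesions$row[k] - 0.5) * config$pixel_size
      cc <- (lesions$col[k] - 0.5) * config$pixel_size
      d2 <- outer((ctr_r - cr)^2, (ctr_c - cc)^2, `+`)
      inside <- d2 <= lesions$radius_um[k]^2
      lesion_id[inside] <- k
      idx <- which(inside)
      if (length(alkene_col) == 1) {
        amp[idx, alkene_col] <- amp[idx, alkene_col] * lesions$alkene_scale[k]
      }
      if (length(amide_col) == 1) {
        amp[idx, amide_col] <- amp[idx, amide_col] *
          lesions$amide1630_scale[k]
      }
    }
  }

  cube <- withr::with_seed(config$seed, {
    y <- amp %*% t(profiles) # npix x n_wn
    if (config$scatter_amplitude > 0) {
      mult <- if (is.null(config$scatter_map)) {
        rep(1, npix)
      } else {
        as.vector(config$scatter_map)
      }
      phase <- runif(npix, 0, 2 * pi)
      wn_n <- (wn - min(wn)) / (max(wn) - min(wn)) # 0..1
      ripple <- sin(outer(rep(2 * pi * 1.25, npix), wn_n) + phase)
      slope <- outer(rep(0.6, npix), wn_n - 0.5)
      y <- y + config$scatter_amplitude * mult * (0.5 * ripple + slope)
    }
    if (config$noise_sd > 0) {
      y <- y + matrix(rnorm(npix * length(wn), sd = config$noise_sd),
        npix, length(wn)
      )
    }
    array(y, c(nr, nc, length(wn)))
  })

  list(
    image = spectral_image(cube, wn, config$pixel_size,
      provenance = if (config$grid == "FTIR") "FTIR" else "QCL"
    ),
    plaque_mask = lesion_id > 0,
    lesion_id = lesion_id
  )
}

#' Synthetic immunofluorescence stain channels for a scene
#'
#' Emits two scalar "stain" images aligned to the scene's ground truth,
#' standing in for the fibril-core probe (ThT-like: bright in the inner
#' half of each lesion) and the anti-amyloid antibody (4G8-like: bright
#' over the full lesion, hence covering the corona). Intensities are
#' `high` inside the stained region and `low` outside, with optional
#' Gaussian noise.
#'
#' @param scene Result of [generate_ir_scene()].
#' @param core_fraction Radius fraction of the lesion painted as core.
#' @param high,low Foreground/background intensity.
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed Integer seed.
#' @return List of matrices `core_channel` and `corona_channel` on the IR
#'   pixel grid.
#' @export
make_stain_images <- function(scene, core_fraction = 0.5, high = 0.9,
                              low = 0.1, noise_sd = 0.02, seed = 1L) {
  lesions <- attr(scene, "lesions")
  id <- scene$lesion_id
  nr <- nrow(id)
  nc <- ncol(id)
  core <- matrix(low, nr, nc)
  corona <- matrix(low, nr, nc)
  corona[id > 0] <- high
  # core: inner disc of each lesion, recovered from the id map by erosion
  # towards the centroid-based radius
  for (k in unique(id[id > 0])) {
    px <- which(id == k, arr.ind = TRUE)
    ctr <- colMeans(px)
    r2 <- max((px[, 1] - ctr[1])^2 + (px[, 2] - ctr[2])^2)
    inner <- (px[, 1] - ctr[1])^2 + (px[, 2] - ctr[2])^2 <=
      r2 * core_fraction^2
    core[px[inner, , drop = FALSE]] <- high
  }
  withr::with_seed(seed, {
    if (noise_sd > 0) {
      core <- core + matrix(rnorm(nr * nc, sd = noise_sd), nr, nc)
      corona <- corona + matrix(rnorm(nr * nc, sd = noise_sd), nr, nc)
    }
    list(core_channel = core, corona_channel = corona)
  })
}
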