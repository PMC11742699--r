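test_that("tile anchors cover the image with flush final tiles", {
  expect_equal(tile_anchors(64, 64, 16), 1L)
  expect_equal(tile_anchors(128, 64, 0), c(1L, 65L))
  # 480-px whole-slide dimension: anchors 0,48,...,384 plus flush 416
  # (1-based here)
  a <- tile_anchors(480, 64, 16)
  expect_equal(a, c(seq(1L, 385L, by = 48L), 417L))
  # brute-force coverage check
  covered <- rep(FALSE, 480)
  for (s in a) covered[s:(s + 63)] <- TRUE
  expect_true(all(covered))
  expect_error(tile_anchors(50, 64, 16), "smaller than the tile")
})

test_that("max-reassembly equals the brute-force per-pixel maximum", {
  # two overlapping constant tiles: overlap takes the larger score
  t1 <- list(row = 1L, col = 1L, scores = matrix(0.3, 4, 4))
  t2 <- list(row = 1L, col = 3L, scores = matrix(0.7, 4, 4))
  am <- assemble_activation(list(t1, t2), c(4, 6))
  expect_true(all(am$scores[, 3:4] == 0.7))
  expect_true(all(am$scores[, 1:2] == 0.3))

  # single tile is the identity
  s <- matrix(runif(16), 4, 4)
  expect_equal(
    assemble_activation(list(list(row = 1L, col = 1L, scores = s)),
      c(4, 4))$scores,
    s
  )

  # fuzz: random tilings against a brute-force per-pixel max oracle
  set.seed(10)
  for (i in 1:100) {
    nr <- sample(8:20, 1)
    nc <- sample(8:20, 1)
    n_tiles <- sample(3:8, 1)
    tiles <- list()
    brute <- matrix(-Inf, nr, nc)
    for (k in seq_len(n_tiles)) {
      th <- sample(2:nr, 1)
      tw <- sample(2:nc, 1)
      r0 <- sample(seq_len(nr - th + 1), 1)
      c0 <- sample(seq_len(nc - tw + 1), 1)
      sc <- matrix(runif(th * tw), th, tw)
      tiles[[k]] <- list(row = r0, col = c0, scores = sc)
      brute[r0:(r0 + th - 1), c0:(c0 + tw - 1)] <- pmax(
        brute[r0:(r0 + th - 1), c0:(c0 + tw - 1)], sc
      )
    }
    if (any(!is.finite(brute))) {
      expect_error(assemble_activation(tiles, c(nr, nc)), "cover")
    } else {
      expect_equal(assemble_activation(tiles, c(nr, nc))$scores, brute)
    }
  }

  expect_error(
    assemble_activation(list(list(row = 1L, col = 1L,
      scores = matrix(0.1, 2, 2))), c(4, 4)),
    "cover"
  )
})

test_that("tiling a WSI yields scoreable tiles whose assembly matches", {
  sc <- generate_ir_scene(ir_scene_config(
    grid = "QCL", image_shape = c(96, 96), noise_sd = 0.002, seed = 12,
    plaque_lesions = tibble::tibble(
      row = 40, col = 55, radius_um = 60,
      alkene_scale = 1, amide1630_scale = 1.5
    )
  ))
  tiles <- tile_wsi(sc$image, tile_size = 64L, overlap = 16L)
  expect_equal(length(tiles), 4) # 2 anchors per dimension (1, 33)
  scored <- score_tiles(tiles, amide_shift_scorer())
  am <- assemble_activation(scored, image_dim(sc$image))
  expect_true(all(am$scores >= 0 & am$scores <= 1))
  # lesion pixels score higher than background pixels
  expect_gt(
    mean(am$scores[sc$plaque_mask]),
    mean(am$scores[!sc$plaque_mask])
  )
  # constant scorer contract: all-ones activation
  ones <- score_tiles(tiles, function(img) {
    matrix(1, image_dim(img)[1], image_dim(img)[2])
  })
  expect_true(all(assemble_activation(ones,
    image_dim(sc$image))$scores == 1))
  # out-of-range scorers violate the contract
  expect_error(
    score_tiles(tiles[1], function(img) {
      matrix(1.5, image_dim(img)[1], image_dim(img)[2])
    }),
    "outside"
  )
})

test_that("binarization thresholds behave at the boundaries", {
  m <- matrix(0, 3, 3)
  expect_false(any(binarize_activation(m)))
  m[2, 2] <- 0.95
  b <- binarize_activation(m, 0.9)
  expect_equal(sum(b), 1)
  expect_true(b[2, 2])
  expect_true(all(binarize_activation(m, 0)))
})

test_that("morphology cascade removes specks and applies the net margin", {
  params <- morph_params()
  expect_false(any(morphological_refine(matrix(FALSE, 10, 10), 4.25,
    params)))

  # a 5-pixel speck at 4.25 um pixels is 90.3 um^2 < 100 um^2: removed
  speck <- matrix(FALSE, 20, 20)
  speck[10, 8:12] <- TRUE
  expect_false(any(morphological_refine(speck, 4.25, params)))

  # disc of radius 20 um at 1 um pixels: survives with ~+5 um net margin
  m <- matrix(FALSE, 80, 80)
  for (i in 1:80) {
    for (j in 1:80) {
      m[i, j] <- (i - 40)^2 + (j - 40)^2 <= 20^2
    }
  }
  ref <- morphological_refine(m, 1, params)
  expect_true(any(ref))
  area <- sum(ref) # pixel count at 1 um^2/px
  expect_lt(abs(area - pi * 25^2) / (pi * 25^2), 0.1)

  # net-margin property across radii: refined radius ~ r + (dilate - erode)
  for (r in c(12, 25)) {
    mm <- matrix(FALSE, 100, 100)
    for (i in 1:100) {
      for (j in 1:100) {
        mm[i, j] <- (i - 50)^2 + (j - 50)^2 <= r^2
      }
    }
    got <- morphological_refine(mm, 1, params)
    r_eff <- sqrt(sum(got) / pi)
    expect_lt(abs(r_eff - (r + 5)), 1)
  }
})

test_that("shape metrics: disc, bar and plus-sign geometry", {
  disc <- which(outer((1:41) - 21, (1:41) - 21,
    function(a, b) a^2 + b^2) <= 15^2, arr.ind = TRUE)
  md <- shape_metrics(disc, pixel_size = 2)
  expect_equal(md$area_um2, nrow(disc) * 4)
  expect_lt(md$eccentricity, 0.1)
  expect_gt(md$solidity, 0.9)

  bar <- cbind(rep(1, 20), 1:20)
  mb <- shape_metrics(bar)
  expect_gt(mb$eccentricity, 0.99)

  plus <- rbind(c(1, 2), c(2, 1), c(2, 2), c(2, 3), c(3, 2))
  mp <- shape_metrics(plus)
  expect_equal(mp$solidity, 5 / 9, tolerance = 1e-9)

  m1 <- shape_metrics(cbind(5, 7))
  expect_equal(m1$eccentricity, 0)
  expect_equal(m1$solidity, 1)
})

test_that("eccentricity/solidity criteria prune elongated objects", {
  m <- matrix(FALSE, 120, 220)
  # compact disc r = 18 px (survives) and a long thin 4 x 150 bar (pruned)
  for (i in 1:120) {
    for (j in 1:120) {
      m[i, j] <- (i - 60)^2 + (j - 60)^2 <= 18^2
    }
  }
  m[58:61, 130:219] <- TRUE
  got <- morphological_refine(m, 1, morph_params())
  lab <- as.matrix(plaquelipids:::label_components(got))
  expect_equal(max(lab), 1)
  px <- which(lab == 1, arr.ind = TRUE)
  expect_lt(shape_metrics(px)$eccentricity, 0.5)
})

test_that("shapes trace component boundaries at pixel-accurate areas", {
  m <- matrix(FALSE, 20, 20)
  m[6:15, 4:13] <- TRUE # 10 x 10 square
  shp <- shapes_from_mask(m, pixel_size = 4.25)
  expect_equal(nrow(shp), 1)
  # exact up to the 4-corner chamfer of the half-pixel contour (0.5 px^2)
  expect_equal(shp$area_um2, (100 - 0.5) * 4.25^2, tolerance = 1e-9)
  # identity transform keeps image micrometre coordinates
  poly <- shp$polygon[[1]]
  expect_equal(range(poly[, "x"]), c(3, 13) * 4.25)
  expect_equal(range(poly[, "y"]), c(5, 15) * 4.25)

  # additivity over disjoint components
  m2 <- m
  m2[2:4, 15:18] <- TRUE
  shp2 <- suppressWarnings(shapes_from_mask(m2, pixel_size = 4.25))
  expect_equal(sum(shp2$area_um2), (100 + 12 - 1) * 4.25^2,
    tolerance = 1e-9)

  # border-touching components are excluded with a warning
  m3 <- m
  m3[1:3, 1:3] <- TRUE
  expect_warning(shp3 <- shapes_from_mask(m3, pixel_size = 4.25), "border")
  expect_equal(nrow(shp3), 1)
})

test_that("Helmert-transformed shapes land in stage coordinates", {
  m <- matrix(FALSE, 20, 20)
  m[6:15, 4:13] <- TRUE
  tf <- fit_helmert_transform(point_pairs(
    cbind(c(0, 1, 0), c(0, 0, 1)), cbind(c(100, 102, 100), c(200, 200, 202))
  )) # scale 2, translation (100, 200)
  shp <- shapes_from_mask(m, pixel_size = 4.25, transform = tf)
  expect_equal(shp$area_um2, (100 - 0.5) * 4.25^2 * 4, tolerance = 1e-9)
  expect_equal(range(shp$polygon[[1]][, "x"]), 100 + 2 * c(3, 13) * 4.25)
})

test_that("shape export round-trips through WKT CSV and GeoJSON", {
  m <- matrix(FALSE, 30, 30)
  m[5:12, 5:12] <- TRUE
  m[18:27, 15:26] <- TRUE
  shp <- shapes_from_mask(m, pixel_size = 4.25)
  expect_equal(nrow(shp), 2)
  for (fmt in c("wkt_csv", "geojson")) {
    f <- withr::local_tempfile(fileext = if (fmt == "geojson") {
      ".geojson"
    } else {
      ".csv"
    })
    export_shapes(shp, f, format = fmt)
    back <- read_shapes(f, format = fmt)
    expect_equal(nrow(back), 2)
    for (k in 1:2) {
      expect_lt(max(abs(back$polygon[[k]] - shp$polygon[[k]])), 1e-6)
      # stored areas agree with shoelace recomputation on read-back
      ring <- back$polygon[[k]]
      ring <- ring[-nrow(ring), , drop = FALSE]
      expect_equal(back$area_um2[k],
        plaquelipids:::shoelace_area(ring),
        tolerance = 1e-6
      )
    }
  }
  # empty sets export a header-only file
  empty <- shapes_from_mask(matrix(FALSE, 5, 5), 1)
  f <- withr::local_tempfile(fileext = ".csv")
  export_shapes(empty, f)
  expect_equal(nrow(read_shapes(f)), 0)
})

test_that("end-to-end detection meets precision/recall 0.9 across seeds", {
  metrics <- purrr::map_dfr(1:20, function(s) {
    sc <- generate_ir_scene(ir_scene_config(
      grid = "QCL", image_shape = c(96, 96), noise_sd = 0.005, seed = s,
      plaque_lesions = tibble::tibble(
        row = c(30, 65), col = c(35, 70), radius_um = c(50, 35),
        alkene_scale = c(1, 1), amide1630_scale = c(1.5, 1.6)
      )
    ))
    tiles <- tile_wsi(sc$image, 64L, 16L)
    am <- assemble_activation(score_tiles(tiles, amide_shift_scorer()),
      image_dim(sc$image))
    detection_metrics(binarize_activation(am, 0.9), sc$plaque_mask)
  })
  expect_true(all(metrics$recall >= 0.9))
  expect_true(all(metrics$precision >= 0.9))
})
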