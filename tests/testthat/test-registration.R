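test_that("affine fits recover known transforms and validate geometry", {
  # identity pairs -> identity transform
  p <- point_pairs(cbind(c(0, 1, 0), c(0, 0, 1)), cbind(c(0, 1, 0), c(0, 0, 1)))
  tf <- fit_affine_transform(p)
  expect_equal(tf$A, diag(2), tolerance = 1e-12)
  expect_equal(tf$t, c(0, 0), tolerance = 1e-12)

  # apply-then-fit round trip to 1e-9
  set.seed(2)
  A <- matrix(c(1.2, -0.3, 0.4, 0.9), 2)
  t <- c(5, -2)
  src <- matrix(runif(20, -10, 10), 10, 2)
  tgt <- src %*% t(A) + matrix(t, 10, 2, byrow = TRUE)
  fit <- fit_affine_transform(point_pairs(src, tgt))
  expect_lt(max(abs(fit$A - A)), 1e-9)
  expect_lt(max(abs(fit$t - t)), 1e-9)
  expect_lt(fit$residual_rms, 1e-9)

  expect_error(
    fit_affine_transform(point_pairs(
      cbind(1:4, 2 * (1:4)), matrix(runif(8), 4, 2)
    )),
    "collinear"
  )
  expect_error(fit_affine_transform(p[1:2, ]), "at least 3")
})

test_that("affine residual RMS scales with noise as least-squares predicts", {
  set.seed(3)
  sigma <- 0.1
  n <- 60
  rels <- replicate(200, {
    src <- matrix(runif(2 * n, -10, 10), n, 2)
    tgt <- src + matrix(rnorm(2 * n, sd = sigma), n, 2)
    fit_affine_transform(point_pairs(src, tgt))$residual_rms
  })
  # E[rms^2] = sigma^2 * (1 - p/n), p = 3 parameters per coordinate
  expect_equal(mean(rels^2), sigma^2 * (1 - 3 / n), tolerance = 0.05)
})

test_that("transform application, inversion and round trips", {
  tf <- fit_affine_transform(point_pairs(
    cbind(c(0, 1, 0, 2), c(0, 0, 1, 2)),
    cbind(c(5, 6, 5, 7), c(5, 5, 6, 7))
  )) # translation by (5, 5)
  expect_equal(apply_transform(tf, cbind(0, 0)),
    cbind(x = 5, y = 5),
    tolerance = 1e-12
  )
  set.seed(4)
  pts <- matrix(rnorm(14), 7, 2)
  rt <- apply_transform(invert_transform(tf), apply_transform(tf, pts))
  expect_lt(max(abs(rt - pts)), 1e-9)
})

test_that("Helmert fit recovers scale, rotation and translation", {
  tf0 <- fit_helmert_transform(point_pairs(
    cbind(c(0, 1, 0), c(0, 0, 1)), cbind(c(0, 1, 0), c(0, 0, 1))
  ))
  expect_equal(tf0$scale, 1, tolerance = 1e-12)
  expect_equal(tf0$rotation, 0, tolerance = 1e-12)
  expect_equal(tf0$t, c(0, 0), tolerance = 1e-12)

  # worked example: scale 2, rotation +90 deg, translation (5, 5)
  tf <- fit_helmert_transform(point_pairs(
    cbind(c(0, 1, 0), c(0, 0, 1)), cbind(c(5, 5, 3), c(5, 7, 5))
  ))
  expect_equal(tf$scale, 2, tolerance = 1e-12)
  expect_equal(tf$rotation, pi / 2, tolerance = 1e-12)
  expect_equal(tf$t, c(5, 5), tolerance = 1e-12)
  expect_lt(tf$residual_rms, 1e-12)

  # conformal: no shear, |det| = scale^2
  expect_equal(det(tf$A), tf$scale^2, tolerance = 1e-12)
  expect_error(
    fit_helmert_transform(point_pairs(
      cbind(c(1, 1), c(2, 2)), cbind(c(0, 1), c(0, 1))
    )),
    "coincident"
  )
})

test_that("noisy Helmert parameter recovery stays within propagated bounds", {
  set.seed(5)
  s <- 1.5
  th <- 0.3
  A <- s * rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  t <- c(100, -50)
  sigma <- 0.05
  n <- 30
  ests <- replicate(100, {
    src <- matrix(runif(2 * n, 0, 50), n, 2)
    tgt <- src %*% t(A) + matrix(t, n, 2, byrow = TRUE) +
      matrix(rnorm(2 * n, sd = sigma), n, 2)
    fit <- fit_helmert_transform(point_pairs(src, tgt))
    c(fit$scale, fit$rotation)
  })
  expect_lt(abs(mean(ests[1, ]) - s), 3 * sd(ests[1, ]) / sqrt(100) + 1e-6)
  expect_lt(abs(mean(ests[2, ]) - th), 3 * sd(ests[2, ]) / sqrt(100) + 1e-6)
})

test_that("point pairs and transforms round-trip through files", {
  p <- point_pairs(cbind(c(0, 3, 1), c(2, 0, 4)), cbind(c(1, 4, 2), c(3, 1, 5)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_point_pairs(p, f)
  expect_equal(as.data.frame(read_point_pairs(f)), as.data.frame(p))
  tf <- fit_helmert_transform(p)
  j <- withr::local_tempfile(fileext = ".json")
  write_transform_json(tf, j)
  back <- read_transform_json(j)
  expect_equal(back$A, tf$A, tolerance = 1e-12)
  expect_equal(back$t, tf$t, tolerance = 1e-12)
  expect_s3_class(back, "helmert_transform2d")
})

test_that("Otsu's threshold equals the exhaustive-search maximizer", {
  # two-valued image: threshold strictly between the modes
  v <- c(rep(0.1, 50), rep(0.9, 50))
  th <- otsu_threshold(v)
  expect_gt(th, 0.1)
  expect_lte(th, 0.9)
  expect_error(otsu_threshold(rep(1, 10)), "constant")

  # brute-force oracle over all 256 bin-edge candidates using raw values
  brute_otsu <- function(v, n_bins = 256) {
    edges <- seq(min(v), max(v), length.out = n_bins + 1)
    cand <- edges[2:n_bins]
    score <- vapply(cand, function(thr) {
      lo <- v < thr
      if (!any(lo) || all(lo)) {
        return(-Inf)
      }
      w0 <- mean(lo)
      (w0 * (1 - w0)) * (mean(v[!lo]) - mean(v[lo]))^2
    }, numeric(1))
    cand[which.max(score)]
  }
  three <- c(rep(0, 50), rep(0.5, 25), rep(1, 50))
  expect_equal(otsu_threshold(three), brute_otsu(three), tolerance = 1e-9)

  set.seed(6)
  for (i in 1:5) {
    v <- c(rnorm(300, 0.2, 0.05), rnorm(300, 0.8, 0.05))
    expect_equal(otsu_threshold(v), brute_otsu(v), tolerance = 0.01)
    # misclassification below 1% against ground-truth labels
    labels <- rep(c(FALSE, TRUE), each = 300)
    expect_lt(mean((v >= otsu_threshold(v)) != labels), 0.01)
  }
})

test_that("region masks partition into disjoint core, corona and ring", {
  sc <- generate_ir_scene(ir_scene_config(
    grid = "FTIR", image_shape = c(60, 60),
    plaque_lesions = tibble::tibble(
      row = c(20, 45), col = c(20, 45), radius_um = c(8, 6),
      alkene_scale = c(0.6, 0.7), amide1630_scale = c(1.5, 1.5)
    )
  ))
  st <- make_stain_images(sc, noise_sd = 0.02, seed = 3)
  identity_tf <- fit_affine_transform(point_pairs(
    cbind(c(1, 60, 1), c(1, 1, 60)), cbind(c(1, 60, 1), c(1, 1, 60))
  ))
  rm <- make_region_masks(st$core_channel, st$corona_channel, identity_tf,
    c(60, 60),
    ring_width_px = 3
  )
  expect_false(any(rm$core & rm$corona))
  expect_false(any((rm$core | rm$corona) & rm$surrounding_ring))
  expect_gt(sum(rm$core), 0)
  expect_gt(sum(rm$corona), 0)
  expect_gt(sum(rm$surrounding_ring), 0)
  # corona channel contained in core channel leaves the corona empty
  rm2 <- make_region_masks(st$core_channel, st$core_channel, identity_tf,
    c(60, 60),
    ring_width_px = 3
  )
  expect_equal(sum(rm2$corona), 0)
})

test_that("ring geometry matches a brute-force disc dilation count", {
  m <- matrix(FALSE, 40, 40)
  ctr <- c(20, 20)
  for (i in 1:40) {
    for (j in 1:40) {
      m[i, j] <- (i - ctr[1])^2 + (j - ctr[2])^2 <= 5^2
    }
  }
  # brute force: pixels within distance 3 of the disc but not in it
  ring_true <- matrix(FALSE, 40, 40)
  disc_px <- which(m, arr.ind = TRUE)
  for (i in 1:40) {
    for (j in 1:40) {
      if (m[i, j]) next
      d2 <- min((disc_px[, 1] - i)^2 + (disc_px[, 2] - j)^2)
      ring_true[i, j] <- d2 <= 3^2
    }
  }
  dil <- as.matrix(EBImage::dilate(
    EBImage::Image(m * 1), plaquelipids:::disc_brush(3)
  )) > 0.5
  ring_got <- dil & !m
  expect_identical(ring_got, ring_true)
})

test_that("region mean spectra are arithmetic means of pixel spectra", {
  sc <- generate_ir_scene(ir_scene_config(
    grid = "QCL", image_shape = c(6, 6), noise_sd = 0.01, seed = 8
  ))
  Y <- as_spectra_matrix(sc$image)
  mask1 <- matrix(FALSE, 6, 6)
  mask1[2, 3] <- TRUE
  got1 <- region_mean_spectrum(sc$image, mask1)
  expect_equal(got1$absorbance, Y[(3 - 1) * 6 + 2, ], tolerance = 1e-12)

  mask2 <- matrix(FALSE, 6, 6)
  mask2[c(5, 30)] <- TRUE
  got2 <- region_mean_spectrum(sc$image, mask2)
  expect_equal(got2$absorbance, (Y[5, ] + Y[30, ]) / 2, tolerance = 1e-12)

  # linearity: mean over a union of two disjoint equal-size masks is the
  # average of the two region means
  maskA <- matrix(FALSE, 6, 6)
  maskA[1:6] <- TRUE
  maskB <- matrix(FALSE, 6, 6)
  maskB[13:18] <- TRUE
  mu <- region_mean_spectrum(sc$image, maskA | maskB)$absorbance
  muA <- region_mean_spectrum(sc$image, maskA)$absorbance
  muB <- region_mean_spectrum(sc$image, maskB)$absorbance
  expect_equal(mu, (muA + muB) / 2, tolerance = 1e-12)

  expect_error(region_mean_spectrum(sc$image, matrix(FALSE, 6, 6)),
    "empty mask")
})

test_that("core unsaturation sits below ring unsaturation on lesions", {
  for (s in 1:5) {
    sc <- generate_ir_scene(ir_scene_config(
      grid = "FTIR", image_shape = c(40, 40), noise_sd = 0.003, seed = s,
      plaque_lesions = tibble::tibble(
        row = 20, col = 20, radius_um = 10,
        alkene_scale = 0.6, amide1630_scale = 1.5
      )
    ))
    st <- make_stain_images(sc, noise_sd = 0.02, seed = s)
    identity_tf <- fit_affine_transform(point_pairs(
      cbind(c(1, 40, 1), c(1, 1, 40)), cbind(c(1, 40, 1), c(1, 1, 40))
    ))
    rm <- make_region_masks(st$core_channel, st$corona_channel, identity_tf,
      c(40, 40),
      ring_width_px = 4
    )
    um <- unsaturation_map(sc$image)
    expect_lt(
      mean(um$ratio[rm$core], na.rm = TRUE),
      mean(um$ratio[rm$surrounding_ring], na.rm = TRUE)
    )
  }
})
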