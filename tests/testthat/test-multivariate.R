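test_that("standardized PCA: identities and sign convention", {
  set.seed(1)
  x <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(NULL, paste0("f", 1:5)))
  pc <- pca_standardized(x)
  expect_true(all(abs(colMeans(pc$scores)) < 1e-10))
  expect_true(all(diff(pc$explained) < 1e-12))
  expect_equal(sum(pc$explained), 1)
  # reconstruction from all components reproduces the standardized matrix
  z <- scale(x)
  recon <- pc$scores %*% t(pc$loadings)
  expect_equal(unname(recon), unname(z[, ]), tolerance = 1e-9)
  # largest-magnitude loading positive in every component
  top <- apply(pc$loadings, 2, function(l) l[which.max(abs(l))])
  expect_true(all(top > 0))
})

test_that("perfectly correlated features load on a single component", {
  x <- cbind(a = 1:6, b = 2 * (1:6) + 3)
  pc <- suppressWarnings(pca_standardized(x))
  expect_equal(pc$explained[1], 1, tolerance = 1e-12)
})

test_that("PC1 recovers the generating axis of an anisotropic cloud", {
  set.seed(7)
  n <- 500
  theta <- pi / 7
  u <- c(cos(theta), sin(theta))
  x <- cbind(rnorm(n, sd = 3)) %*% rbind(u) +
    matrix(rnorm(2 * n, sd = 0.4), n, 2)
  colnames(x) <- c("x", "y")
  pc <- pca_standardized(x)
  # map the first component back to the data scale (loadings act on
  # standardized columns) and compare directions there
  v <- pc$loadings[, 1] * apply(x, 2, sd)
  v <- v / sqrt(sum(v^2))
  ang <- acos(min(1, abs(sum(v * u))))
  expect_lt(ang * 180 / pi, 2)
})

test_that("zero-variance features are dropped with a warning", {
  x <- cbind(a = rnorm(5), b = rnorm(5), c = rep(1, 5))
  expect_warning(pc <- pca_standardized(x), "zero-variance")
  expect_equal(nrow(pc$loadings), 2)
  expect_error(pca_standardized(cbind(a = 1:3)), "at least 2")
})

test_that("linear separator: symmetric clusters split along the midline", {
  set.seed(3)
  x <- rbind(
    cbind(rnorm(20, -1, 0.1), rnorm(20, 0, 0.5)),
    cbind(rnorm(20, +1, 0.1), rnorm(20, 0, 0.5))
  )
  colnames(x) <- c("PC1", "PC2")
  y <- rep(c("a", "b"), each = 20)
  sep <- fit_linear_separator(x, y, cost = 100)
  expect_equal(sep$training_accuracy, 1)
  # boundary ~ vertical line through 0: w dominated by the first coordinate,
  # crossing point near 0
  expect_gt(abs(sep$weights[1]), 10 * abs(sep$weights[2]))
  expect_lt(abs(-sep$offset / sep$weights[1]), 0.2)
})

test_that("inseparable layouts report sub-100% accuracy without error", {
  x <- cbind(PC1 = c(0, 1, 0, 1), PC2 = c(0, 1, 1, 0))
  y <- c("a", "a", "b", "b") # XOR
  sep <- fit_linear_separator(x, y)
  expect_lt(sep$training_accuracy, 1)
  expect_error(fit_linear_separator(x, rep("a", 4)), "two classes")
})

test_that("cohort plaque and surrounding lipidomes separate in PC space", {
  coh <- generate_lipidome_cohort(cohort_config(seed = 21))
  prof <- composition_profile(exclude_species(coh, quiet = TRUE))
  pca <- lipidome_pca(prof, groups = c("plaque", "surrounding"))
  sc <- pca$scores[pca$meta$sample_id, 1:2, drop = FALSE]
  sep <- fit_linear_separator(sc, pca$meta$tissue_group)
  expect_equal(sep$training_accuracy, 1)
})

test_that("species correlations match the closed-form Pearson r", {
  mk <- function(id, v) {
    tibble::tibble(
      sample_id = id, case_id = id, tissue_group = "plaque",
      species_name = c("PC 32:0", "PC 34:1", "PC 38:4"),
      concentration_pmol = v
    )
  }
  samples <- dplyr::bind_rows(
    mk("s1", c(1, 2, 7)), mk("s2", c(2, 4, 4)),
    mk("s3", c(3, 6, 3)), mk("s4", c(4, 8, 1))
  )
  prof <- composition_profile(samples)
  cm <- species_correlation_matrix(prof, "PC 32:0")
  wide <- tidyr::pivot_wider(prof$species,
    names_from = species_name, values_from = mol_percent
  )
  want <- cor(wide$`PC 32:0`, wide$`PC 38:4`)
  expect_equal(cm$r["PC 32:0", "PC 38:4"], want, tolerance = 1e-12)
  expect_true(is.na(cm$r["PC 32:0", "PC 32:0"])) # self masked
  td <- tidy(cm)
  expect_true(all(abs(td$r[!is.na(td$r)]) <= 1))
})

test_that("duplicated and negated profiles give r = 1 and r = -1", {
  mk <- function(id, a) {
    tibble::tibble(
      sample_id = id, case_id = id, tissue_group = "plaque",
      species_name = c("PC 32:0", "PC 32:1", "PC 34:1"),
      # PC 32:1 duplicates PC 32:0; PC 34:1 takes the complement
      concentration_pmol = c(a, a, 100 - 2 * a)
    )
  }
  prof <- composition_profile(dplyr::bind_rows(
    mk("s1", 10), mk("s2", 20), mk("s3", 30)
  ))
  cm <- species_correlation_matrix(prof, "PC 32:0")
  expect_equal(cm$r["PC 32:0", "PC 32:1"], 1, tolerance = 1e-12)
  expect_equal(cm$r["PC 32:0", "PC 34:1"], -1, tolerance = 1e-12)
})
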