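#' Standardized PCA via singular value decomposition
#'
#' Columns are centered and scaled to unit variance (so the decomposition
#' is of the correlation matrix), then decomposed by SVD. Zero-variance
#' columns are dropped with a warning. Loadings follow the sign convention
#' that each component's largest-magnitude loading is positive.
#'
#' @param x Numeric matrix or data frame, samples in rows, features in
#'   columns.
#' @return A `pca_standardized` object with elements `scores` (zero
#'   column-mean), `loadings`, `sdev`, `explained` (fractions of total
#'   variance, nonincreasing) and `dropped` (names of constant features).
#' @export
pca_standardized <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("need at least 2 samples and 2 features", call. = FALSE)
  }
  v <- apply(x, 2, stats::var)
  dropped <- colnames(x)[v == 0]
  if (length(dropped) > 0) {
    warning(
      "dropping zero-variance feature(s): ",
      paste(utils::head(dropped, 5), collapse = ", "),
      if (length(dropped) > 5) ", ..." else "",
      call. = FALSE
    )
    x <- x[, v > 0, drop = FALSE]
  }
  if (ncol(x) < 2) stop("fewer than 2 informative features", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  # sign convention: largest-|loading| entry positive per component
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  rotation <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  structure(
    list(
      scores = scores,
      loadings = rotation,
      sdev = pc$sdev,
      explained = pc$sdev^2 / sum(pc$sdev^2),
      dropped = dropped
    ),
    class = "pca_standardized"
  )
}

#' @export
print.pca_standardized <- function(x, ...) {
  cat(
    "<pca_standardized> ", nrow(x$scores), " samples, ",
    nrow(x$loadings), " features; PC1/PC2 explain ",
    sprintf("%.1f%% / %.1f%%", 100 * x$explained[1], 100 * x$explained[2]),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn pca_standardized Scores in long-friendly wide form, one row
#'   per sample.
#' @param x A `pca_standardized` object.
#' @param ... Unused.
#' @export
tidy.pca_standardized <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "sample_id")
}

#' @describeIn pca_standardized One row per component with sdev and
#'   explained-variance fraction.
#' @export
glance.pca_standardized <- function(x, ...) {
  tibble::tibble(
    component = paste0("PC", seq_along(x$explained)),
    sdev = x$sdev,
    explained = x$explained,
    cumulative = cumsum(x$explained)
  )
}

#' PCA of lipidome compositions
#'
#' Convenience wrapper: builds the samples x species mol% matrix from a
#' profiled cohort (after lyso/standard exclusion) restricted to the given
#' tissue groups and runs [pca_standardized()].
#'
#' @param profile A [composition_profile()].
#' @param groups Tissue groups to include.
#' @return A `pca_standardized` object with an extra `meta` tibble
#'   (`sample_id`, `case_id`, `tissue_group`).
#' @export
lipidome_pca <- function(profile, groups = c("plaque", "surrounding")) {
  stopifnot(inherits(profile, "composition_profile"))
  sp <- dplyr::filter(profile$species, .data$tissue_group %in% groups)
  wide <- sp |>
    dplyr::select("sample_id", "species_name", "mol_percent") |>
    tidyr::pivot_wider(
      names_from = "species_name", values_from = "mol_percent",
      values_fill = 0
    )
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$sample_id
  out <- pca_standardized(m)
  out$meta <- sp |>
    dplyr::distinct(.data$sample_id, .data$case_id, .data$tissue_group) |>
    dplyr::arrange(match(.data$sample_id, wide$sample_id))
  out
}

#' Maximum-margin linear separator (linear SVM)
#'
#' Fits a linear support vector machine in a low-dimensional score space
#' (e.g., the first two principal components), as used to draw the
#' separation line between plaque and surrounding lipidomes. Soft margin
#' with default penalty `cost = 1`; for separable classes the fitted
#' boundary is the maximum-margin one for any sufficiently large cost.
#'
#' @param scores Numeric matrix/data frame of coordinates (rows = samples).
#' @param labels Factor or vector with exactly two classes.
#' @param cost Soft-margin penalty.
#' @return A `linear_separator` with `weights`, `offset` (decision rule
#'   `sign(w . x + offset)`), `training_accuracy` and `levels`.
#' @export
fit_linear_separator <- function(scores, labels, cost = 1) {
  scores <- as.matrix(scores)
  labels <- factor(labels)
  if (nlevels(labels) != 2) {
    stop("need exactly two classes", call. = FALSE)
  }
  if (any(table(labels) < 2)) {
    stop("need >= 2 points per class", call. = FALSE)
  }
  fit <- e1071::svm(
    x = scores, y = labels, kernel = "linear", cost = cost, scale = FALSE
  )
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  pred <- predict(fit, scores)
  structure(
    list(
      weights = w,
      offset = b,
      training_accuracy = mean(pred == labels),
      levels = levels(labels),
      svm = fit
    ),
    class = "linear_separator"
  )
}

#' @export
print.linear_separator <- function(x, ...) {
  cat(
    "<linear_separator> ", paste(x$levels, collapse = " vs "),
    "; training accuracy ", sprintf("%.1f%%", 100 * x$training_accuracy),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn fit_linear_separator Decision-boundary coefficients.
#' @param x A `linear_separator`.
#' @param ... Unused.
#' @export
tidy.linear_separator <- function(x, ...) {
  tibble::tibble(
    term = c(names(x$weights), "(offset)"),
    value = c(unname(x$weights), x$offset)
  )
}

#' Predict side of a linear separator
#'
#' @param object A `linear_separator`.
#' @param newdata Coordinates matrix.
#' @param ... Unused.
#' @return Factor of predicted class labels.
#' @export
predict.linear_separator <- function(object, newdata, ...) {
  predict(object$svm, as.matrix(newdata))
}

#' Correlation of anchor species with all species
#'
#' Pearson correlation (with two-sided p-values) of each anchor species'
#' mol% against every species' mol% across samples of one tissue group,
#' mirroring the saturated-PC correlation matrix analysis.
#' Self-correlations and zero-variance species are masked (`NA`).
#'
#' @param profile A [composition_profile()].
#' @param anchor_species Character vector of anchor species names.
#' @param group Tissue group across which to correlate (default plaque).
#' @param species Optional restriction of the correlated species set (e.g.
#'   all PC species); default all species in the profile.
#' @return A `species_correlation` object with matrices `r` and `p`
#'   (anchors x species) and a tidy accessor.
#' @export
species_correlation_matrix <- function(profile, anchor_species,
                                       group = "plaque", species = NULL) {
  stopifnot(inherits(profile, "composition_profile"))
  sp <- dplyr::filter(profile$species, .data$tissue_group %in% group)
  wide <- sp |>
    dplyr::select("sample_id", "species_name", "mol_percent") |>
    tidyr::pivot_wider(
      names_from = "species_name", values_from = "mol_percent",
      values_fill = 0
    )
  if (nrow(wide) < 3) stop("need >= 3 samples", call. = FALSE)
  m <- as.matrix(wide[, -1])
  if (is.null(species)) species <- colnames(m)
  missing_anchor <- setdiff(anchor_species, colnames(m))
  if (length(missing_anchor) > 0) {
    stop(
      "anchor species not in profile: ",
      paste(missing_anchor, collapse = ", "),
      call. = FALSE
    )
  }
  species <- intersect(species, colnames(m))
  r <- matrix(NA_real_, length(anchor_species), length(species),
    dimnames = list(anchor_species, species)
  )
  p <- r
  for (a in anchor_species) {
    for (s in species) {
      if (s == a) next
      xa <- m[, a]
      xs <- m[, s]
      if (stats::sd(xa) == 0 || stats::sd(xs) == 0) next
      ct <- stats::cor.test(xa, xs, method = "pearson")
      r[a, s] <- unname(ct$estimate)
      p[a, s] <- ct$p.value
    }
  }
  structure(
    list(r = r, p = p, group = group, n = nrow(m)),
    class = "species_correlation"
  )
}

#' @export
print.species_correlation <- function(x, ...) {
  cat(
    "<species_correlation> ", nrow(x$r), " anchor(s) x ", ncol(x$r),
    " species over ", x$n, " ", paste(x$group, collapse = "/"),
    " samples\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn species_correlation_matrix One row per (anchor, species)
#'   pair with `r`, `p` and a `strong` flag (|r| >= 0.6 and p <= 0.05).
#' @param x A `species_correlation`.
#' @param ... Unused.
#' @export
tidy.species_correlation <- function(x, ...) {
  out <- tidyr::expand_grid(
    anchor = rownames(x$r), species = colnames(x$r)
  )
  out$r <- as.vector(t(x$r))
  out$p <- as.vector(t(x$p))
  dplyr::mutate(out,
    strong = !is.na(.data$r) & abs(.data$r) >= 0.6 & .data$p <= 0.05
  )
}
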