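#' Plot a composition profile
#'
#' Double-bond or carbon-number distributions as grouped bars
#' (mean +/- SD over the samples of each tissue group).
#'
#' @param object A [composition_profile()].
#' @param bin_type `"db"` or `"carbon"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.composition_profile <- function(object, bin_type = c("db", "carbon"),
                                         ...) {
  bin_type <- match.arg(bin_type)
  dat <- tidy(object) |>
    dplyr::filter(.data$bin_type == .env$bin_type) |>
    dplyr::group_by(.data$tissue_group, .data$bin) |>
    dplyr::summarise(
      mean = mean(.data$mol_percent),
      sd = stats::sd(.data$mol_percent),
      .groups = "drop"
    )
  xlab <- if (bin_type == "db") {
    "C=C double bonds per lipid"
  } else {
    "total acyl carbons per lipid"
  }
  ggplot2::ggplot(dat, ggplot2::aes(
    x = factor(.data$bin), y = .data$mean, fill = .data$tissue_group
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd
      ),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::labs(x = xlab, y = "mol %", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot paired plaque-minus-surrounding differences
#'
#' Per-bin mean paired difference with SD error bars and significance
#' stars from the Welch comparison.
#'
#' @param object A [group_difference_profile()].
#' @param bin_type `"db"`, `"carbon"` or `"species"` (species shows the
#'   top contributors by absolute difference).
#' @param top_n Species shown when `bin_type = "species"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.group_difference_profile <- function(object,
                                              bin_type = c(
                                                "db", "carbon", "species"
                                              ),
                                              top_n = 9, ...) {
  bin_type <- match.arg(bin_type)
  dat <- dplyr::filter(object$paired, .data$bin_type == .env$bin_type)
  if (bin_type == "species") {
    dat <- dat |>
      dplyr::arrange(dplyr::desc(abs(.data$mean_diff))) |>
      utils::head(top_n)
    dat$bin <- factor(dat$bin, levels = dat$bin)
  } else {
    dat$bin <- factor(dat$bin, levels = sort(as.numeric(unique(dat$bin))))
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin, y = .data$mean_diff)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_diff - .data$sd_diff,
        ymax = .data$mean_diff + .data$sd_diff
      ),
      width = 0.25
    ) +
    ggplot2::geom_text(
      ggplot2::aes(
        label = .data$stars,
        y = .data$mean_diff + sign(.data$mean_diff) *
          (.data$sd_diff + 0.1)
      ),
      size = 3
    ) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = NULL, y = "plaque - surrounding (percentage points)"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(
      angle = if (bin_type == "species") 45 else 0, hjust = 1
    ))
}

#' Plot PCA scores with an optional separation line
#'
#' @param object A [pca_standardized()] result (e.g. from
#'   [lipidome_pca()], whose group metadata colors the points).
#' @param separator Optional [fit_linear_separator()] on PC1/PC2 scores.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pca_standardized <- function(object, separator = NULL, ...) {
  dat <- tibble::tibble(
    sample_id = rownames(object$scores),
    PC1 = object$scores[, 1],
    PC2 = object$scores[, 2]
  )
  if (!is.null(object$meta)) {
    dat <- dplyr::left_join(dat, object$meta, by = "sample_id")
  }
  aes <- if ("tissue_group" %in% names(dat)) {
    ggplot2::aes(.data$PC1, .data$PC2, colour = .data$tissue_group)
  } else {
    ggplot2::aes(.data$PC1, .data$PC2)
  }
  p <- ggplot2::ggplot(dat, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2]),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  if (!is.null(separator)) {
    w <- separator$weights
    b <- separator$offset
    if (abs(w[2]) > 1e-12) {
      p <- p + ggplot2::geom_abline(
        intercept = -b / w[2], slope = -w[1] / w[2], linetype = 2
      )
    } else {
      p <- p + ggplot2::geom_vline(xintercept = -b / w[1], linetype = 2)
    }
  }
  p
}

map_to_tibble <- function(m) {
  tibble::tibble(
    row = rep(seq_len(nrow(m)), ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
}

#' Plot an unsaturation map
#'
#' @param object An [unsaturation_map()].
#' @param ... Unused.
#' @return A ggplot raster of the per-pixel A3012/A1738 index.
#' @export
autoplot.unsaturation_map <- function(object, ...) {
  dat <- map_to_tibble(object$ratio)
  ggplot2::ggplot(dat, ggplot2::aes(.data$col, .data$row,
    fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "A3012/A1738") +
    ggplot2::theme_minimal()
}

#' Plot an activation map
#'
#' @param object An activation map from [assemble_activation()].
#' @param ... Unused.
#' @return A ggplot raster of per-pixel plaque scores.
#' @export
autoplot.activation_map <- function(object, ...) {
  dat <- map_to_tibble(object$scores)
  ggplot2::ggplot(dat, ggplot2::aes(.data$col, .data$row,
    fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "score") +
    ggplot2::theme_minimal()
}

#' Plot a species correlation matrix
#'
#' Anchors on rows, species on columns; strong significant correlations
#' (|r| >= 0.6, p <= 0.05) are marked.
#'
#' @param object A [species_correlation_matrix()] result.
#' @param ... Unused.
#' @return A ggplot heatmap.
#' @export
autoplot.species_correlation <- function(object, ...) {
  dat <- tidy(object)
  dat$species <- factor(dat$species, levels = colnames(object$r))
  ggplot2::ggplot(dat, ggplot2::aes(.data$species, .data$anchor,
    fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      data = dplyr::filter(dat, .data$strong),
      ggplot2::aes(label = "*"), size = 3
    ) +
    ggplot2::scale_fill_gradient2(
      low = "steelblue", mid = "white", high = "firebrick",
      limits = c(-1, 1), na.value = "grey90"
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
      vjust = 0.5, hjust = 1))
}
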