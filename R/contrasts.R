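#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test as used for all group comparisons in the
#' workflow: `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with
#' Welch-Satterthwaite degrees of freedom, no multiple-testing adjustment.
#' Computed in closed form so that zero-variance groups (exact synthetic
#' compositions) degrade gracefully; agrees with
#' `stats::t.test(var.equal = FALSE)` wherever the latter is defined.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return A one-row tibble with `estimate` (mean of `a` minus mean of `b`),
#'   `t`, `df` and `p`.
#' @examples
#' welch_t(c(10, 12, 14), c(11, 13, 15, 17))
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  n1 <- length(a)
  n2 <- length(b)
  v1 <- stats::var(a)
  v2 <- stats::var(b)
  est <- mean(a) - mean(b)
  if (v1 == 0 && v2 == 0) {
    if (est == 0) {
      return(tibble::tibble(estimate = 0, t = 0, df = NA_real_, p = 1))
    }
    stop("both groups have zero variance", call. = FALSE)
  }
  se2 <- v1 / n1 + v2 / n2
  t <- est / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  tibble::tibble(
    estimate = est,
    t = t,
    df = df,
    p = 2 * stats::pt(-abs(t), df)
  )
}

significance_stars <- function(p) {
  dplyr::case_when(
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 1e-2 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Paired and group-wise composition contrasts
#'
#' Computes, for every double-bond bin, carbon bin and species:
#' * the paired plaque-minus-surrounding difference per AD case, summarized
#'   as mean +/- SD over cases (matching the paired panels of the study
#'   design), and
#' * Welch t statistics for the unpaired plaque-vs-surrounding comparison
#'   and, when control samples are present, each AD group vs control.
#'
#' Cases lacking either member of the plaque/surrounding pair are excluded
#' with a warning.
#'
#' @param profile A [composition_profile()], or a long species table which
#'   is profiled first.
#' @return A `group_difference_profile` object: tibbles `paired`
#'   (`bin_type`, `bin`, `mean_diff`, `sd_diff`, `n_pairs`, Welch `t`, `df`,
#'   `p`, `stars`), `paired_cases` (per-case differences), and `vs_control`.
#' @export
group_difference_profile <- function(profile) {
  if (!inherits(profile, "composition_profile")) {
    profile <- composition_profile(profile)
  }
  long <- dplyr::bind_rows(
    tidy(profile) |> dplyr::mutate(bin = as.character(.data$bin)),
    profile$species |>
      dplyr::mutate(bin_type = "species") |>
      dplyr::rename(bin = "species_name")
  )
  if (!all(c("case_id", "tissue_group") %in% names(long))) {
    stop("profile lacks case_id/tissue_group metadata", call. = FALSE)
  }

  paired_wide <- long |>
    dplyr::filter(.data$tissue_group %in% c("plaque", "surrounding")) |>
    dplyr::select("case_id", "tissue_group", "bin_type", "bin",
      "mol_percent") |>
    tidyr::pivot_wider(
      names_from = "tissue_group", values_from = "mol_percent",
      values_fill = 0
    )
  have_both <- long |>
    dplyr::filter(.data$tissue_group %in% c("plaque", "surrounding")) |>
    dplyr::distinct(.data$case_id, .data$tissue_group) |>
    dplyr::count(.data$case_id) |>
    dplyr::filter(.data$n == 2) |>
    dplyr::pull(.data$case_id)
  dropped <- setdiff(unique(paired_wide$case_id), have_both)
  if (length(dropped) > 0) {
    warning(
      "excluding unpaired case(s): ", paste(dropped, collapse = ", "),
      call. = FALSE
    )
    paired_wide <- dplyr::filter(paired_wide, .data$case_id %in% have_both)
  }
  if (length(have_both) < 2) {
    stop("need >= 2 cases with paired plaque/surrounding samples",
      call. = FALSE
    )
  }
  paired_cases <- paired_wide |>
    dplyr::mutate(diff = .data$plaque - .data$surrounding)

  # degenerate bins (zero variance in both groups, e.g. noise-free synthetic
  # cohorts) are reported with NA statistics instead of failing the profile
  safe_welch <- function(a, b) {
    tryCatch(welch_t(a, b), error = function(e) {
      tibble::tibble(
        estimate = mean(a) - mean(b), t = NA_real_, df = NA_real_,
        p = NA_real_
      )
    })
  }
  welch_by_bin <- function(data, g1, g2) {
    data |>
      dplyr::group_by(.data$bin_type, .data$bin) |>
      dplyr::summarise(
        welch = list(
          safe_welch(
            .data$mol_percent[.data$tissue_group == g1],
            .data$mol_percent[.data$tissue_group == g2]
          )
        ),
        .groups = "drop"
      ) |>
      tidyr::unnest("welch")
  }

  paired <- paired_cases |>
    dplyr::group_by(.data$bin_type, .data$bin) |>
    dplyr::summarise(
      mean_diff = mean(.data$diff),
      sd_diff = stats::sd(.data$diff),
      n_pairs = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      welch_by_bin(
        dplyr::filter(long, .data$case_id %in% have_both),
        "plaque", "surrounding"
      ) |>
        dplyr::select("bin_type", "bin", "t", "df", "p"),
      by = c("bin_type", "bin")
    ) |>
    dplyr::mutate(stars = significance_stars(.data$p))

  vs_control <- NULL
  if ("control" %in% long$tissue_group) {
    vs_control <- dplyr::bind_rows(
      welch_by_bin(long, "plaque", "control") |>
        dplyr::mutate(comparison = "plaque_vs_control"),
      welch_by_bin(long, "surrounding", "control") |>
        dplyr::mutate(comparison = "surrounding_vs_control")
    ) |>
      dplyr::mutate(stars = significance_stars(.data$p))
  }

  structure(
    list(
      paired = paired,
      paired_cases = paired_cases,
      vs_control = vs_control
    ),
    class = "group_difference_profile"
  )
}

#' @export
print.group_difference_profile <- function(x, ...) {
  cat("<group_difference_profile> paired plaque - surrounding, ",
    x$paired$n_pairs[1], " case pairs\n",
    sep = ""
  )
  print(dplyr::filter(x$paired, .data$bin_type == "db"), n = 8)
  invisible(x)
}

#' @describeIn group_difference_profile Tidy per-bin paired summary.
#' @param x A `group_difference_profile`.
#' @param ... Unused.
#' @export
tidy.group_difference_profile <- function(x, ...) {
  x$paired
}
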