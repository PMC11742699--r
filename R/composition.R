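#' Exclude species that cannot enter two-chain composition analysis
#'
#' Removes lysophospholipids (single-chain species, not comparable with
#' two-chain lipids) and isotope-labeled internal standards from a species
#' concentration table, reporting the removed mass fraction.
#'
#' @param samples Long tibble with at least `sample_id`, `species_name` and
#'   `concentration_pmol`.
#' @param drop_lyso,drop_labeled Which exclusion rules to apply.
#' @param quiet Suppress the removed-fraction message.
#' @return The filtered tibble; the per-sample removed mass fraction is
#'   attached as attribute `"excluded_fraction"`.
#' @export
exclude_species <- function(samples, drop_lyso = TRUE, drop_labeled = TRUE,
                            quiet = FALSE) {
  stopifnot(all(c("sample_id", "species_name", "concentration_pmol")
  %in% names(samples)))
  info <- parse_lipid_shorthand(unique(samples$species_name))
  drop <- (drop_lyso & info$is_lyso) | (drop_labeled & info$is_labeled_standard)
  drop_names <- info$species_name[drop]
  kept <- dplyr::filter(samples, !(.data$species_name %in% drop_names))

  removed <- samples |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      removed_fraction = sum(
        .data$concentration_pmol[.data$species_name %in% drop_names]
      ) / sum(.data$concentration_pmol),
      .groups = "drop"
    )
  empty <- setdiff(unique(samples$sample_id), unique(kept$sample_id))
  if (length(empty) > 0) {
    stop(
      "no analyzable species left after exclusion in sample(s): ",
      paste(empty, collapse = ", "),
      call. = FALSE
    )
  }
  if (!quiet && any(removed$removed_fraction > 0)) {
    message(sprintf(
      "exclude_species: removed %.2f%% of total molar content (%d species)",
      100 * mean(removed$removed_fraction), length(drop_names)
    ))
  }
  attr(kept, "excluded_fraction") <- removed
  kept
}

#' Normalize samples to molar composition
#'
#' Converts per-species molar concentrations to mol% of the total molar
#' lipid content of each sample, so samples of different total lipid mass
#' become comparable.
#'
#' @param samples Long tibble with `sample_id`, `species_name` and
#'   `concentration_pmol`.
#' @return The tibble with an added `mol_percent` column; within each sample
#'   `mol_percent` sums to 100.
#' @export
normalize_molar <- function(samples) {
  stopifnot(all(c("sample_id", "concentration_pmol") %in% names(samples)))
  if (any(samples$concentration_pmol < 0)) {
    stop("negative concentrations", call. = FALSE)
  }
  out <- samples |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(total = sum(.data$concentration_pmol)) |>
    dplyr::ungroup()
  if (any(out$total <= 0)) {
    bad <- unique(out$sample_id[out$total <= 0])
    stop(
      "zero total molar content in sample(s): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  out |>
    dplyr::mutate(mol_percent = 100 * .data$concentration_pmol / .data$total) |>
    dplyr::select(-"total")
}

#' Double-bond and chain-length composition profiles
#'
#' Aggregates per-species mol% into the two sum-composition views used
#' throughout the workflow: the distribution over the number of C=C double
#' bonds per lipid (bins 0-7) and over the total acyl carbon number (even
#' bins 30-44). Species outside the reporting bins are retained in the
#' totals and reported under their observed bin value (no renormalization),
#' so each distribution always sums to 100.
#'
#' Two scalar summaries are computed per sample: `ufa_percent`, the
#' unsaturated-lipid percentage (100 minus the saturated DB0 bin), and
#' `mean_chain_length`, the mol%-weighted mean total acyl carbon number.
#'
#' @param samples Long species table. If it has no `mol_percent` column it
#'   is passed through [normalize_molar()] first (it is not passed through
#'   [exclude_species()]; apply exclusion rules explicitly).
#' @return A `composition_profile` object: list of tibbles `db`
#'   (sample x double-bond bin), `carbon` (sample x carbon bin), `species`
#'   (sample x species mol%), and `summary` (per-sample scalars).
#' @examples
#' cohort <- generate_lipidome_cohort(cohort_config(seed = 1))
#' prof <- cohort |> exclude_species(quiet = TRUE) |> composition_profile()
#' head(prof$summary)
#' @export
composition_profile <- function(samples) {
  if (!"mol_percent" %in% names(samples)) {
    samples <- normalize_molar(samples)
  }
  meta_cols <- intersect(c("sample_id", "case_id", "tissue_group"),
    names(samples))
  info <- parse_lipid_shorthand(unique(samples$species_name))
  x <- dplyr::left_join(samples, info, by = "species_name")

  species <- x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(meta_cols)),
      .data$species_name) |>
    dplyr::summarise(mol_percent = sum(.data$mol_percent), .groups = "drop")

  db <- x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(meta_cols)),
      db = .data$total_double_bonds) |>
    dplyr::summarise(mol_percent = sum(.data$mol_percent), .groups = "drop") |>
    complete_bins(meta_cols, "db", db_bins())

  carbon <- x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(meta_cols)),
      carbon = .data$total_carbons) |>
    dplyr::summarise(mol_percent = sum(.data$mol_percent), .groups = "drop") |>
    complete_bins(meta_cols, "carbon", carbon_bins())

  summary <- dplyr::left_join(
    db |>
      dplyr::group_by(dplyr::across(dplyr::all_of(meta_cols))) |>
      dplyr::summarise(
        ufa_percent = 100 - sum(.data$mol_percent[.data$db == 0]),
        .groups = "drop"
      ),
    carbon |>
      dplyr::group_by(dplyr::across(dplyr::all_of(meta_cols))) |>
      dplyr::summarise(
        mean_chain_length =
          sum(.data$carbon * .data$mol_percent) / sum(.data$mol_percent),
        .groups = "drop"
      ),
    by = meta_cols
  )

  structure(
    list(db = db, carbon = carbon, species = species, summary = summary),
    class = "composition_profile"
  )
}

# ensure every reporting bin appears (zero-filled) for every sample while
# keeping observed out-of-range bins
complete_bins <- function(tbl, meta_cols, bin_col, bins) {
  meta <- dplyr::distinct(tbl, dplyr::across(dplyr::all_of(meta_cols)))
  all_bins <- sort(unique(c(bins, tbl[[bin_col]])))
  grid <- tidyr::expand_grid(meta, ..bin.. = all_bins)
  names(grid)[names(grid) == "..bin.."] <- bin_col
  out <- dplyr::left_join(grid, tbl, by = c(meta_cols, bin_col))
  out$mol_percent[is.na(out$mol_percent)] <- 0
  dplyr::arrange(out, dplyr::across(dplyr::all_of(c(meta_cols, bin_col))))
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(
    "<composition_profile> ", nrow(x$summary), " samples, ",
    length(unique(x$species$species_name)), " species\n",
    sep = ""
  )
  print(x$summary, n = 6)
  invisible(x)
}

#' @describeIn composition_profile Long tidy view; one row per sample, bin
#'   type and bin, plus the scalar summaries as bin type `"summary"`.
#' @param x A `composition_profile`.
#' @param ... Unused.
#' @export
tidy.composition_profile <- function(x, ...) {
  dplyr::bind_rows(
    x$db |>
      dplyr::mutate(bin_type = "db") |>
      dplyr::rename(bin = "db"),
    x$carbon |>
      dplyr::mutate(bin_type = "carbon") |>
      dplyr::rename(bin = "carbon")
  ) |>
    dplyr::mutate(bin = as.integer(.data$bin)) |>
    dplyr::select(dplyr::any_of(c(
      "sample_id", "case_id", "tissue_group", "bin_type", "bin", "mol_percent"
    )))
}
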