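#' Default tissue-group composition targets
#'
#' The default calibration of the synthetic lipidome cohort. For each tissue
#' group (plaque, surrounding, control) it fixes the mol% distribution over
#' double-bond bins 0-7 and over even total-acyl-carbon bins 30-44. The
#' printed anchors of the study conditions are hit exactly or within their
#' stated uncertainty:
#'
#' * saturated (DB0) paired effect plaque - surrounding = +1.6 pp, DB2
#'   effect = -1.8 pp (the most negative bin);
#' * unsaturated-lipid content 88.6% (plaque) and 90.2% (surrounding),
#'   consistent with the group means 88 +/- 1 and 91 +/- 1 and with the
#'   paired +1.6 pp effect, which cannot all hold as exact equalities;
#' * mean chain length 36.76 C (plaque) and 37.02 C (surrounding); C32
#'   paired effect +1.9 pp (largest positive); C30 mean 0.85% (smallest
#'   bin); grand means DB1 = 36%, DB3 = 1.3% (minimum of DB1-7).
#'
#' Unprinted bins are free parameters set once to a plausible human
#' grey-matter lipidome (abundant DB4/DB6 from arachidonoyl and
#' docosahexaenoyl species, sparse DB3/DB5).
#'
#' @return A tibble with columns `tissue_group`, `bin_type` (`"db"` or
#'   `"carbon"`), `bin` (integer) and `target` (mol%). Within each group and
#'   bin type the targets sum to 100.
#' @export
default_group_bin_targets <- function() {
  db_bins <- 0:7
  carbon_bins <- seq(30L, 44L, by = 2L)
  db <- list(
    plaque      = c(11.40, 35.90, 14.00, 1.27, 16.95, 4.10, 14.05, 2.33),
    surrounding = c(9.80, 36.00, 15.80, 1.32, 17.00, 3.95, 13.90, 2.23),
    control     = c(10.60, 36.10, 15.20, 1.31, 17.05, 3.95, 13.75, 2.04)
  )
  carbon <- list(
    plaque      = c(0.95, 7.90, 23.10, 24.85, 18.45, 15.25, 7.25, 2.25),
    surrounding = c(0.75, 6.00, 22.25, 25.00, 19.00, 15.75, 8.00, 3.25),
    control     = c(0.85, 6.20, 21.50, 25.00, 19.00, 16.00, 8.10, 3.35)
  )
  groups <- names(db)
  dplyr::bind_rows(
    purrr::map_dfr(groups, function(g) {
      tibble::tibble(
        tissue_group = g, bin_type = "db", bin = db_bins,
        target = db[[g]]
      )
    }),
    purrr::map_dfr(groups, function(g) {
      tibble::tibble(
        tissue_group = g, bin_type = "carbon", bin = carbon_bins,
        target = carbon[[g]]
      )
    })
  )
}

#' Default species panel seed
#'
#' Shorthand names and seed abundance weights for the synthetic lipidome
#' panel. The panel spans PC, ether PC, PE, PS, PI, SM, Cer and HexCer and
#' covers total carbons 30-44 and 0-7 double bonds. Seed weights encode the
#' realistic coupling between chain length and unsaturation (short species
#' are saturated, long species polyunsaturated); group joints are obtained
#' from this seed by iterative proportional fitting to the group bin
#' targets, so the weights set the dependence structure, not the marginals.
#'
#' @return A tibble with `species_name` and `seed_weight`.
#' @export
default_species_seed <- function() {
  tibble::tribble(
    ~species_name, ~seed_weight,
    # fully saturated, short
    "PC 30:0", 0.5,
    "PC 32:0", 5.5,
    "PC 34:0", 2.2,
    "PE 34:0", 0.4,
    "PC 36:0", 0.6,
    "PS 36:0", 0.2,
    "Cer 18:0;O2/20:0", 0.3,
    # monounsaturated
    "PC 30:1", 0.3,
    "PC 32:1", 1.6,
    "PC 34:1", 8.5,
    "PE 34:1", 0.8,
    "PC O-34:1", 0.7,
    "PC 36:1", 4.5,
    "PE 36:1", 1.2,
    "SM 18:1;O2/18:0", 3.2,
    "HexCer 18:1;O2/18:0", 0.3,
    "PE 38:1", 0.8,
    "SM 18:1;O2/20:0", 0.9,
    "SM 18:1;O2/22:0", 0.8,
    "PC 40:1", 0.3,
    "SM 18:1;O2/24:0", 1.3,
    "PC 42:1", 0.2,
    # two double bonds
    "PC 32:2", 0.3,
    "PC 34:2", 2.8,
    "PC 36:2", 3.6,
    "PE 36:2", 1.4,
    "PC O-36:2", 0.5,
    "PC 38:2", 1.0,
    "PE 38:2", 0.8,
    "PC 40:2", 0.5,
    "SM 18:1;O2/22:1", 0.6,
    "SM 18:1;O2/24:1", 2.4,
    "HexCer 18:1;O2/24:1", 0.4,
    "PC 44:2", 0.4,
    # three double bonds (sparse in grey matter)
    "PC 34:3", 0.1,
    "PC 36:3", 0.4,
    "PC 38:3", 0.3,
    "PE 38:3", 0.2,
    "PC 40:3", 0.2,
    "PC 42:3", 0.1,
    # four double bonds (arachidonoyl-rich)
    "PC 34:4", 0.2,
    "PC 36:4", 2.5,
    "PE 36:4", 0.8,
    "PC 38:4", 5.5,
    "PE 38:4", 3.5,
    "PI 38:4", 2.0,
    "PC 40:4", 1.0,
    "PE 40:4", 1.2,
    "PE 42:4", 0.3,
    "PC 44:4", 0.4,
    # five double bonds
    "PC 38:5", 1.0,
    "PE 38:5", 0.7,
    "PC 40:5", 0.9,
    "PE 40:5", 0.9,
    "PE 42:5", 0.3,
    "PC 44:5", 0.2,
    # six double bonds (docosahexaenoyl-rich)
    "PC 38:6", 1.8,
    "PE 38:6", 1.5,
    "PC 40:6", 3.0,
    "PE 40:6", 5.5,
    "PS 40:6", 1.8,
    "PE 42:6", 0.4,
    "PC 44:6", 0.3,
    # seven double bonds
    "PE 40:7", 1.0,
    "PC 40:7", 0.4,
    "PE 42:7", 0.5,
    "PC 44:7", 0.3
  )
}

#' Configuration for the synthetic lipidome cohort
#'
#' Bundles everything [generate_lipidome_cohort()] needs: cohort sizes, the
#' per-group bin targets, the species-level paired effect enforced on
#' PC 32:0, the noise model and the seed.
#'
#' The noise model is logistic-normal at the level of (carbon, double-bond)
#' cells: each case draws one perturbation shared by its paired plaque and
#' surrounding samples (`sigma_case`, healthy controls scaled by
#' `hc_case_scale`) and each sample adds an independent perturbation
#' (`sigma_sample`); perturbed cell masses are renormalized to 100.
#' `noise_sd_scale = 0` reproduces the targets exactly. Defaults were set
#' from the printed dispersions of the study conditions (group SD ~1 pp on
#' the saturated bin, paired-difference SD ~0.5 pp).
#'
#' @param n_ad_cases,n_hc_cases Number of AD cases (each contributing a
#'   paired plaque + surrounding sample) and of healthy-control cases.
#' @param group_bin_targets Tibble as returned by
#'   [default_group_bin_targets()].
#' @param species_seed Tibble as returned by [default_species_seed()].
#' @param species_effects Named numeric vector of species-level paired
#'   plaque-minus-surrounding effects (pp) enforced exactly at zero noise.
#' @param noise_sd_scale Global multiplier on both noise scales.
#' @param sigma_case,sigma_sample Log-scale SDs of the case-shared and
#'   sample-specific perturbations.
#' @param hc_case_scale Multiplier on `sigma_case` for healthy controls.
#' @param total_pmol_meanlog,total_pmol_sdlog Log-normal parameters of the
#'   per-sample total molar lipid amount (pmol).
#' @param seed Integer seed; same seed, same cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_ad_cases = 8L,
                          n_hc_cases = 8L,
                          group_bin_targets = default_group_bin_targets(),
                          species_seed = default_species_seed(),
                          species_effects = c("PC 32:0" = 1.8),
                          noise_sd_scale = 1,
                          sigma_case = 0.12,
                          sigma_sample = 0.045,
                          hc_case_scale = 2,
                          total_pmol_meanlog = log(2e5),
                          total_pmol_sdlog = 0.25,
                          seed = 20260101L) {
  stopifnot(
    n_ad_cases >= 1, n_hc_cases >= 0,
    noise_sd_scale >= 0, sigma_case >= 0, sigma_sample >= 0,
    hc_case_scale >= 0
  )
  groups <- c("plaque", "surrounding", "control")
  for (g in groups) {
    for (bt in c("db", "carbon")) {
      tg <- group_bin_targets$target[
        group_bin_targets$tissue_group == g & group_bin_targets$bin_type == bt
      ]
      if (length(tg) == 0) {
        stop("group_bin_targets missing ", bt, " targets for group '", g, "'",
          call. = FALSE
        )
      }
      if (any(tg < 0)) {
        stop("negative ", bt, " target for group '", g, "'", call. = FALSE)
      }
      if (abs(sum(tg) - 100) > 1e-6) {
        stop(bt, " targets for group '", g, "' sum to ", sum(tg),
          ", expected 100",
          call. = FALSE
        )
      }
    }
  }
  structure(
    list(
      n_ad_cases = as.integer(n_ad_cases),
      n_hc_cases = as.integer(n_hc_cases),
      group_bin_targets = group_bin_targets,
      species_seed = species_seed,
      species_effects = species_effects,
      noise_sd_scale = noise_sd_scale,
      sigma_case = sigma_case,
      sigma_sample = sigma_sample,
      hc_case_scale = hc_case_scale,
      total_pmol_meanlog = total_pmol_meanlog,
      total_pmol_sdlog = total_pmol_sdlog,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(
    "<cohort_config> ", x$n_ad_cases, " AD cases (paired plaque/surrounding), ",
    x$n_hc_cases, " HC cases; noise_sd_scale = ", x$noise_sd_scale,
    ", seed = ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}
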