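#' Generate a synthetic lipidome cohort
#'
#' Simulates species-level molar concentration tables for a cohort of
#' `n_ad_cases` AD cases (each with a paired plaque and surrounding-tissue
#' sample) and `n_hc_cases` healthy-control cases (one grey-matter sample
#' each). Per-sample compositions are the group joint (carbon, double-bond)
#' tables perturbed by logistic-normal noise (see [cohort_config()]);
#' species within a cell split the cell mass by fixed panel weights.
#'
#' At `noise_sd_scale = 0` every sample's aggregated double-bond and
#' carbon-bin profiles equal the configured group targets exactly, and the
#' paired PC 32:0 difference equals the configured species effect.
#'
#' @param config A [cohort_config()].
#' @return A long tibble with columns `sample_id`, `case_id`,
#'   `tissue_group` (plaque/surrounding/control), `species_name` and
#'   `concentration_pmol`. The species panel is attached as attribute
#'   `"panel"`.
#' @examples
#' cohort <- generate_lipidome_cohort(cohort_config(seed = 1))
#' dplyr::count(cohort, tissue_group)
#' @export
generate_lipidome_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  panel <- build_species_panel(config)
  joints <- group_joint_tables(config, panel)

  cell_key <- paste(panel$total_carbons, panel$total_double_bonds, sep = ":")
  cells <- unique(cell_key)
  cell_mass <- function(joint) {
    cb <- as.character(carbon_bins())
    db <- as.character(db_bins())
    vapply(strsplit(cells, ":"), function(cd) {
      joint[match(cd[1], cb), match(cd[2], db)]
    }, numeric(1))
  }
  masses <- lapply(joints, cell_mass) # per group: mass per cell, sums to 100

  n_cells <- length(cells)
  s_case <- config$noise_sd_scale * config$sigma_case
  s_samp <- config$noise_sd_scale * config$sigma_sample

  sample_rows <- function(sample_id, case_id, group, z_case) {
    z <- z_case + s_samp * rnorm(n_cells)
    m <- masses[[group]] * exp(z)
    m <- 100 * m / sum(m)
    conc_total <- exp(rnorm(1, config$total_pmol_meanlog,
      sd = config$total_pmol_sdlog
    ))
    species_molpct <- m[match(cell_key, cells)] * panel$cell_weight
    tibble::tibble(
      sample_id = sample_id,
      case_id = case_id,
      tissue_group = group,
      species_name = panel$species_name,
      concentration_pmol = conc_total * species_molpct / 100
    )
  }

  out <- withr::with_seed(config$seed, {
    rows <- list()
    for (i in seq_len(config$n_ad_cases)) {
      case <- sprintf("AD%02d", i)
      z_case <- s_case * rnorm(n_cells)
      rows[[length(rows) + 1]] <- sample_rows(
        paste0(case, "_plaque"), case, "plaque", z_case
      )
      rows[[length(rows) + 1]] <- sample_rows(
        paste0(case, "_surrounding"), case, "surrounding", z_case
      )
    }
    for (i in seq_len(config$n_hc_cases)) {
      case <- sprintf("HC%02d", i)
      z_case <- config$hc_case_scale * s_case * rnorm(n_cells)
      rows[[length(rows) + 1]] <- sample_rows(
        paste0(case, "_control"), case, "control", z_case
      )
    }
    dplyr::bind_rows(rows)
  })
  attr(out, "panel") <- panel
  out
}

#' Write / read a cohort species table
#'
#' Plain-CSV interchange format for species-level molar concentration
#' tables: columns `sample_id`, `case_id`, `tissue_group`, `species_name`,
#' `concentration_pmol`.
#'
#' @param cohort Tibble as returned by [generate_lipidome_cohort()].
#' @param path File path.
#' @return `write_cohort_csv()` returns `path` invisibly; `read_cohort_csv()`
#'   returns the cohort tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  req <- c(
    "sample_id", "case_id", "tissue_group", "species_name",
    "concentration_pmol"
  )
  stopifnot(all(req %in% names(cohort)))
  readr::write_csv(cohort[, req], path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    case_id = readr::col_character(),
    tissue_group = readr::col_character(),
    species_name = readr::col_character(),
    concentration_pmol = readr::col_double()
  ))
}
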