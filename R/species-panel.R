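#' Build the synthetic species panel
#'
#' Parses the configured species seed into a panel of lipid species with
#' class, total carbons, total double bonds and base weights, and checks
#' that every bin carrying target mass in the calibration is reachable by
#' at least one species.
#'
#' @param config A [cohort_config()].
#' @return A tibble with columns `species_name`, `lipid_class`,
#'   `total_carbons`, `total_double_bonds`, `base_weight` (panel-wide
#'   weights summing to 1) and `cell_weight` (weights summing to 1 within
#'   each (carbon, double-bond) cell).
#' @export
build_species_panel <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  parsed <- parse_lipid_shorthand(config$species_seed$species_name)
  panel <- dplyr::bind_cols(
    parsed,
    tibble::tibble(seed_weight = config$species_seed$seed_weight)
  )
  if (any(panel$seed_weight < 0)) {
    stop("species seed weights must be nonnegative", call. = FALSE)
  }
  gp_classes <- c("PC", "PC O", "PE", "PS", "PI")
  odd_gp <- panel$lipid_class %in% gp_classes & panel$total_carbons %% 2 != 0
  if (any(odd_gp)) {
    stop(
      "glycerophospholipid species with odd carbon count: ",
      paste(panel$species_name[odd_gp], collapse = ", "),
      call. = FALSE
    )
  }

  # every calibrated bin with positive mass must be coverable
  tg <- config$group_bin_targets
  for (g in unique(tg$tissue_group)) {
    db_t <- tg[tg$tissue_group == g & tg$bin_type == "db", ]
    miss_db <- db_t$bin[db_t$target > 0 &
      !(db_t$bin %in% panel$total_double_bonds)]
    if (length(miss_db) > 0) {
      stop(
        "unreachable double-bond bin ", paste(miss_db, collapse = ", "),
        " for group '", g, "': target mass > 0 but no panel species",
        call. = FALSE
      )
    }
    c_t <- tg[tg$tissue_group == g & tg$bin_type == "carbon", ]
    miss_c <- c_t$bin[c_t$target > 0 & !(c_t$bin %in% panel$total_carbons)]
    if (length(miss_c) > 0) {
      stop(
        "unreachable carbon bin ", paste(miss_c, collapse = ", "),
        " for group '", g, "': target mass > 0 but no panel species",
        call. = FALSE
      )
    }
  }

  panel |>
    dplyr::group_by(.data$total_carbons, .data$total_double_bonds) |>
    dplyr::mutate(cell_weight = .data$seed_weight / sum(.data$seed_weight)) |>
    dplyr::ungroup() |>
    dplyr::mutate(base_weight = .data$seed_weight / sum(.data$seed_weight)) |>
    dplyr::select(
      "species_name", "lipid_class", "total_carbons", "total_double_bonds",
      "base_weight", "cell_weight"
    )
}

#' Iterative proportional fitting of a nonnegative matrix to given margins
#'
#' Rescales rows and columns of `seed` alternately until its row and column
#' sums match `row_targets` and `col_targets`. Zero cells stay zero, so the
#' seed's support (and its dependence structure, in the odds-ratio sense) is
#' preserved.
#'
#' @param seed Nonnegative matrix.
#' @param row_targets,col_targets Nonnegative target margins; must have
#'   equal totals.
#' @param tol Convergence tolerance on the largest absolute margin error.
#' @param max_iter Iteration cap.
#' @return A matrix of the same dimension with the requested margins.
#' @export
ipf_fit <- function(seed, row_targets, col_targets, tol = 1e-10,
                    max_iter = 5000L) {
  stopifnot(
    is.matrix(seed), all(seed >= 0),
    length(row_targets) == nrow(seed),
    length(col_targets) == ncol(seed)
  )
  if (abs(sum(row_targets) - sum(col_targets)) > 1e-8) {
    stop("row and column targets have different totals", call. = FALSE)
  }
  # rows with zero target are cleared; rows with positive target need support
  if (any(row_targets > 0 & rowSums(seed) == 0)) {
    stop("positive row target with empty seed support", call. = FALSE)
  }
  if (any(col_targets > 0 & colSums(seed) == 0)) {
    stop("positive column target with empty seed support", call. = FALSE)
  }
  x <- seed
  x[row_targets == 0, ] <- 0
  x[, col_targets == 0] <- 0
  for (it in seq_len(max_iter)) {
    rs <- rowSums(x)
    scale_r <- ifelse(rs > 0, row_targets / rs, 0)
    x <- x * scale_r
    cs <- colSums(x)
    scale_c <- ifelse(cs > 0, col_targets / cs, 0)
    x <- sweep(x, 2, scale_c, `*`)
    err <- max(abs(rowSums(x) - row_targets), abs(colSums(x) - col_targets))
    if (err < tol) {
      return(x)
    }
  }
  stop(
    "iterative proportional fitting did not converge (margin error ",
    signif(err, 3), "); the seed support cannot carry the requested margins",
    call. = FALSE
  )
}

carbon_bins <- function() seq(30L, 44L, by = 2L)
db_bins <- function() 0:7

# seed joint over (carbon, double-bond) cells, aggregated from the panel
panel_seed_joint <- function(panel) {
  cb <- carbon_bins()
  db <- db_bins()
  m <- matrix(0, length(cb), length(db), dimnames = list(cb, db))
  for (i in seq_len(nrow(panel))) {
    ci <- match(panel$total_carbons[i], cb)
    di <- match(panel$total_double_bonds[i], db)
    if (is.na(ci) || is.na(di)) {
      stop(
        "panel species '", panel$species_name[i],
        "' falls outside the calibrated bins", call. = FALSE
      )
    }
    m[ci, di] <- m[ci, di] + panel$base_weight[i]
  }
  m
}

# per-group joint cell tables; enforces the PC 32:0 species effect with a
# margin-preserving 2x2 transfer on the (C32,DB0)x(C34,DB1) block
group_joint_tables <- function(config, panel) {
  seed <- panel_seed_joint(panel)
  tg <- config$group_bin_targets
  joints <- list()
  for (g in c("plaque", "surrounding", "control")) {
    ct <- tg$target[tg$tissue_group == g & tg$bin_type == "carbon"]
    dt <- tg$target[tg$tissue_group == g & tg$bin_type == "db"]
    joints[[g]] <- ipf_fit(seed, ct, dt)
  }
  eff <- config$species_effects
  if (!is.null(eff) && "PC 32:0" %in% names(eff)) {
    i32 <- match(32L, carbon_bins())
    i34 <- match(34L, carbon_bins())
    j0 <- match(0L, db_bins())
    j1 <- match(1L, db_bins())
    cur <- joints$plaque[i32, j0] - joints$surrounding[i32, j0]
    delta <- unname(eff[["PC 32:0"]]) - cur
    jp <- joints$plaque
    jp[i32, j0] <- jp[i32, j0] + delta
    jp[i34, j0] <- jp[i34, j0] - delta
    jp[i32, j1] <- jp[i32, j1] - delta
    jp[i34, j1] <- jp[i34, j1] + delta
    if (any(jp < 0)) {
      stop(
        "species effect for PC 32:0 (", eff[["PC 32:0"]],
        " pp) drives a joint cell negative; reduce the effect",
        call. = FALSE
      )
    }
    joints$plaque <- jp
  }
  joints
}
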