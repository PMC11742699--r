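# Generator of the calibrated synthetic lipidome cohort.

test_that("default bin targets are valid compositions with the designed contrasts", {
  tg <- default_group_bin_targets()
  sums <- tg |>
    dplyr::group_by(tissue_group, bin_type) |>
    dplyr::summarise(s = sum(target), .groups = "drop")
  expect_true(all(abs(sums$s - 100) < 1e-9))

  get <- function(g, bt) tg$target[tg$tissue_group == g & tg$bin_type == bt]
  eff_db <- get("plaque", "db") - get("surrounding", "db")
  expect_equal(eff_db[1], 1.6) # saturated bin increase
  expect_equal(eff_db[3], -1.8) # two-double-bond bin, strongest decrease
  expect_equal(which.min(eff_db), 3L)
  eff_c <- get("plaque", "carbon") - get("surrounding", "carbon")
  expect_equal(eff_c[2], 1.9) # C32 strongest increase
  expect_equal(which.max(eff_c), 2L)
  expect_true(all(abs(c(sum(eff_db), sum(eff_c))) < 1e-9))
})

test_that("species panel covers the calibrated bins and is deterministic", {
  cfg <- cohort_config(seed = 7)
  panel <- build_species_panel(cfg)
  expect_true(all(0:7 %in% panel$total_double_bonds))
  expect_true(all(seq(30, 44, 2) %in% panel$total_carbons))
  expect_equal(sum(panel$base_weight), 1)
  # within-cell weights are conditional distributions
  cw <- panel |>
    dplyr::group_by(total_carbons, total_double_bonds) |>
    dplyr::summarise(s = sum(cell_weight), .groups = "drop")
  expect_true(all(abs(cw$s - 1) < 1e-12))
  expect_identical(panel, build_species_panel(cohort_config(seed = 7)))
})

test_that("a single-bin calibration yields a panel reaching that bin", {
  tg <- default_group_bin_targets()
  # collapse all mass onto DB0 / C32: the panel must hold a 32:0 species
  tg$target <- ifelse(
    (tg$bin_type == "db" & tg$bin == 0) |
      (tg$bin_type == "carbon" & tg$bin == 32), 100, 0
  )
  cfg <- cohort_config(group_bin_targets = tg, species_effects = NULL)
  panel <- build_species_panel(cfg)
  expect_true(any(panel$total_carbons == 32 & panel$total_double_bonds == 0))
  expect_true("PC 32:0" %in% panel$species_name)
})

test_that("unreachable calibrated bins raise a configuration error", {
  cfg <- cohort_config()
  seed <- cfg$species_seed[
    parse_lipid_shorthand(cfg$species_seed$species_name)$total_carbons != 30,
  ]
  cfg2 <- cohort_config(species_seed = seed)
  expect_error(build_species_panel(cfg2), "unreachable carbon bin 30")
})

test_that("iterative proportional fitting matches margins and keeps support", {
  set.seed(42)
  for (i in 1:5) {
    seed <- matrix(runif(30), 5, 6)
    seed[sample(30, 8)] <- 0
    x0 <- matrix(rexp(30), 5, 6) * (seed > 0)
    rt <- rowSums(x0)
    ct <- colSums(x0)
    fit <- ipf_fit(seed, rt, ct)
    expect_equal(rowSums(fit), rt, tolerance = 1e-8)
    expect_equal(colSums(fit), ct, tolerance = 1e-8)
    expect_true(all(fit[seed == 0] == 0))
  }
  expect_error(ipf_fit(matrix(1, 2, 2), c(1, 2), c(1, 1)), "different totals")
})

test_that("zero-noise cohort reproduces group targets exactly", {
  coh <- generate_lipidome_cohort(cohort_config(seed = 3, noise_sd_scale = 0))
  prof <- composition_profile(coh)
  tg <- default_group_bin_targets()
  got_db <- prof$db |>
    dplyr::group_by(tissue_group, db) |>
    dplyr::summarise(m = mean(mol_percent), .groups = "drop")
  for (g in c("plaque", "surrounding", "control")) {
    want <- tg$target[tg$tissue_group == g & tg$bin_type == "db"]
    expect_equal(got_db$m[got_db$tissue_group == g], want, tolerance = 1e-9)
  }
  # paired species effect holds exactly at zero noise
  d <- group_difference_profile(prof)
  pc <- d$paired[d$paired$bin_type == "species" & d$paired$bin == "PC 32:0", ]
  expect_equal(pc$mean_diff, 1.8, tolerance = 1e-9)
  expect_equal(pc$sd_diff, 0, tolerance = 1e-9)
})

test_that("cohort layout, positivity and determinism", {
  cfg <- cohort_config(seed = 11)
  coh <- generate_lipidome_cohort(cfg)
  counts <- dplyr::count(dplyr::distinct(coh, sample_id, tissue_group),
    tissue_group)
  expect_equal(
    counts$n[match(c("plaque", "surrounding", "control"),
      counts$tissue_group)],
    c(8L, 8L, 8L)
  )
  expect_true(all(coh$concentration_pmol > 0))
  expect_identical(coh, generate_lipidome_cohort(cohort_config(seed = 11)))
  coh2 <- generate_lipidome_cohort(cohort_config(seed = 12))
  expect_false(isTRUE(all.equal(coh$concentration_pmol,
    coh2$concentration_pmol)))
  # per-sample mol% closes to 100 after normalization
  sums <- normalize_molar(coh) |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(s = sum(mol_percent))
  expect_true(all(abs(sums$s - 100) < 1e-9))
})

test_that("paired saturated-bin effect recovers the configured +1.6 pp", {
  # Monte-Carlo over seeds: mean of per-seed paired DB0 differences must sit
  # within 3 SEM of the configured effect
  effs <- vapply(1:20, function(s) {
    coh <- generate_lipidome_cohort(cohort_config(seed = s))
    d <- group_difference_profile(
      composition_profile(exclude_species(coh, quiet = TRUE))
    )
    d$paired$mean_diff[d$paired$bin_type == "db" & d$paired$bin == "0"]
  }, numeric(1))
  sem <- sd(effs) / sqrt(length(effs))
  expect_lt(abs(mean(effs) - 1.6), 3 * sem + 1e-12)
})

test_that("healthy controls spread wider than AD groups", {
  spreads <- sapply(1:8, function(s) {
    prof <- composition_profile(
      generate_lipidome_cohort(cohort_config(seed = 100 + s))
    )
    x <- prof$summary
    c(
      hc = var(x$ufa_percent[x$tissue_group == "control"]),
      ad = var(x$ufa_percent[x$tissue_group == "plaque"])
    )
  })
  # HC between-case variance exceeds AD within-group variance on average
  # (4x scale by construction) and in most realizations
  expect_gt(mean(spreads["hc", ]), mean(spreads["ad", ]))
  expect_gte(sum(spreads["hc", ] > spreads["ad", ]), 6)
})

test_that("cohort CSV round-trips", {
  coh <- generate_lipidome_cohort(cohort_config(seed = 5, n_ad_cases = 2,
    n_hc_cases = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, path)
  back <- read_cohort_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(coh[, names(back)]),
    tolerance = 1e-12, ignore_attr = TRUE)
})
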