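# Shared default-calibration cohort pipeline, computed once per test run.
default_cohort_results <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- generate_lipidome_cohort(cohort_config())
      profile <- composition_profile(exclude_species(cohort, quiet = TRUE))
      cache <<- list(
        cohort = cohort,
        profile = profile,
        differences = group_difference_profile(profile)
      )
    }
    cache
  }
})
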