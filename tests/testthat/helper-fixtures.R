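# Fixture builders shared across the suite. All data are generated in code;
# nothing binary is stored.

# One complete experiment: wild-type control (f_vehicle = 23/25 = 0.92,
# f_aspirin = 23/50 = 0.46, dumping index 0.5) plus a mutant
# (f_vehicle = 18/20 = 0.90, f_aspirin = 9/50 = 0.18, dumping index 0.2,
# normalized index -0.3).
minimal_screen_df <- function(experiment_id = "E1", mutant = "mutA") {
  tibble::tibble(
    experiment_id = experiment_id,
    genotype = c("yw", "yw", mutant, mutant),
    treatment = c("vehicle", "aspirin", "vehicle", "aspirin"),
    aspirin_mM = c(0, 1.5, 0, 1.5),
    n_s10b = c(2L, 27L, 2L, 41L),
    n_s11 = c(0L, 0L, 0L, 0L),
    n_s12 = c(5L, 0L, 6L, 4L),
    n_s13_14 = c(18L, 23L, 12L, 5L)
  )
}

write_minimal_csv <- function(path = tempfile(fileext = ".csv"),
                              df = minimal_screen_df()) {
  readr::write_csv(df, path)
  path
}

# Hand-assembled per-experiment score table (bypasses score_screen) for
# aggregation unit tests.
scores_tbl <- function(genotype, di, norm = di - 0.5, qc = TRUE) {
  tibble::tibble(
    experiment_id = sprintf("E%d", seq_along(di)),
    genotype = genotype,
    f_vehicle = 0.9, f_aspirin = di * 0.9,
    dumping_index = di, normalized_index = norm,
    is_control = genotype == "yw", qc_pass = qc
  )
}

# Small calibrated simulation config: wild-type control plus optional
# planted genotypes, assay defaults (92% vehicle dumping, aspirin dose at
# half-maximal wild-type maturation, wells of 20-30 follicles).
base_config <- function(genotypes = NULL, tau = 0, n_experiments = 5, seed = 101) {
  sim_screen_config(
    genotypes = genotypes, tau = tau,
    n_experiments = n_experiments, seed = seed
  )
}
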