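test_that("dumping fraction counts S12 and S13/14 as dumped", {
  expect_equal(dumping_fraction(2, 0, 5, 18), 23 / 25)
  expect_equal(dumping_fraction(10, 0, 0, 0), 0)
  expect_equal(dumping_fraction(0, 5, 0, 5), 0.5) # S11 is not dumped
  expect_equal(dumping_fraction(c(2, 10), c(0, 0), c(5, 0), c(18, 0)),
               c(0.92, 0))
  expect_error(dumping_fraction(0, 0, 0, 0), "no follicles")
  expect_error(dumping_fraction(-1, 0, 0, 2), "non-negative")
})

test_that("dumping index is the aspirin-to-vehicle ratio, undefined at 0 vehicle", {
  expect_equal(dumping_index(0.46, 0.92), 0.5)
  x <- runif(20, 0.05, 1)
  expect_equal(dumping_index(x, x), rep(1, 20))
  expect_error(dumping_index(0.3, 0), "undefined")
})

test_that("dumping index is scale-free in the underlying tallies", {
  set.seed(11)
  for (i in 1:25) {
    tal <- rbinom(4, 12, 0.5) + c(1L, 0L, 1L, 0L) # ensure nonzero totals
    for (k in c(2L, 5L, 13L)) {
      f1 <- dumping_fraction(tal[1], tal[2], tal[3], tal[4])
      f2 <- dumping_fraction(k * tal[1], k * tal[2], k * tal[3], k * tal[4])
      expect_equal(f1, f2)
    }
  }
})

test_that("QC band is inclusive at 0.4 and 0.6", {
  expect_true(qc_experiment(0.505))
  expect_false(qc_experiment(0.39))
  expect_true(qc_experiment(0.40))
  expect_true(qc_experiment(0.60))
  expect_false(qc_experiment(0.601))
  expect_equal(qc_experiment(c(0.2, 0.5, 0.8)), c(FALSE, TRUE, FALSE))
})

test_that("normalization subtracts the within-experiment control", {
  expect_equal(normalize_index(0.25, 0.50), -0.25)
  expect_equal(normalize_index(0.50, 0.50), 0)
})

test_that("score_screen computes indices, normalization, and carries QC", {
  tbl <- as_screen_table(minimal_screen_df())
  sc <- score_screen(tbl)
  ctrl <- sc[sc$genotype == "yw", ]
  mut <- sc[sc$genotype == "mutA", ]
  expect_equal(ctrl$dumping_index, 0.5)
  expect_equal(mut$dumping_index, 0.2)
  expect_equal(mut$normalized_index, -0.3)
  expect_equal(ctrl$normalized_index, 0)
  expect_true(all(sc$qc_pass))
})

test_that("a QC-failing control marks every record of the experiment", {
  df <- minimal_screen_df()
  # control aspirin well now 15/50 = 0.30 -> control DI 0.326 < 0.4
  df[df$genotype == "yw" & df$treatment == "aspirin",
     c("n_s10b", "n_s11", "n_s12", "n_s13_14")] <-
    tibble::tibble(n_s10b = 35L, n_s11 = 0L, n_s12 = 0L, n_s13_14 = 15L)
  sc <- score_screen(as_screen_table(df))
  expect_equal(sc$dumping_index[sc$genotype == "yw"], 0.326, tolerance = 1e-3)
  expect_true(all(sc$qc_pass == FALSE))
  expect_equal(nrow(aggregate_genotypes(sc)), 0)
})

test_that("an empty table scores to an empty result", {
  sc <- score_screen(minimal_screen_df()[0, ])
  expect_equal(nrow(sc), 0)
  expect_true(all(c("dumping_index", "normalized_index", "qc_pass") %in% names(sc)))
})

test_that("a control with zero vehicle dumping makes the experiment unusable", {
  df <- minimal_screen_df()
  df[df$genotype == "yw" & df$treatment == "vehicle",
     c("n_s10b", "n_s11", "n_s12", "n_s13_14")] <-
    tibble::tibble(n_s10b = 25L, n_s11 = 0L, n_s12 = 0L, n_s13_14 = 0L)
  sc <- score_screen(as_screen_table(df))
  expect_true(all(is.na(sc$qc_pass)))
  expect_true(any(grepl("unusable", attr(sc, "dropped"))))
  expect_error(aggregate_genotypes(sc, genotype = "mutA"), "no usable")
})

test_that("aggregation uses sample SD and reports missing SD at n = 1", {
  sc <- scores_tbl(rep("mutA", 3), di = c(0.4, 0.5, 0.6))
  agg <- aggregate_genotypes(sc)
  expect_equal(agg$mean_di, 0.5)
  expect_equal(agg$sd_di, 0.1)
  expect_equal(agg$n, 3L)
  expect_false(agg$provisional)

  one <- aggregate_genotypes(scores_tbl("mutB", di = 0.55))
  expect_equal(one$n, 1L)
  expect_true(is.na(one$sd_di) && is.na(one$sd_norm))
  expect_true(one$provisional)
})

test_that("aggregation is invariant to replicate order", {
  di <- c(0.42, 0.61, 0.55, 0.47, 0.58)
  a <- aggregate_genotypes(scores_tbl(rep("g", 5), di))
  perm <- sample(5)
  sc2 <- scores_tbl(rep("g", 5), di[perm])
  sc2$experiment_id <- sprintf("E%d", perm) # keep (experiment, value) pairs
  b <- aggregate_genotypes(sc2)
  expect_equal(a[c("mean_di", "sd_di", "mean_norm", "sd_norm")],
               b[c("mean_di", "sd_di", "mean_norm", "sd_norm")])
})

test_that("balanced screens obey the normalization identity", {
  # with exactly one paired control per experiment,
  # mean(normalized) = mean(DI_genotype) - mean(DI_control)
  for (seed in 1:5) {
    cfg <- base_config(
      genotypes = sim_genotype("g1", beta = 0.5, direction = "enhancer"),
      tau = 0.15, n_experiments = 8, seed = seed
    )
    sc <- score_screen(simulate_screen(cfg))
    for (keep_qc in c(TRUE, FALSE)) {
      sub <- if (keep_qc) sc[sc$qc_pass, ] else sc
      eids <- intersect(sub$experiment_id[sub$is_control],
                        sub$experiment_id[sub$genotype == "g1"])
      sub <- sub[sub$experiment_id %in% eids, ]
      lhs <- mean(sub$normalized_index[sub$genotype == "g1"])
      rhs <- mean(sub$dumping_index[sub$genotype == "g1"]) -
        mean(sub$dumping_index[sub$is_control])
      expect_equal(lhs, rhs, tolerance = 1e-12)
    }
  }
})
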