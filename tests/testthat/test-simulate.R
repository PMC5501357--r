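small_cfg <- function(...) {
  args <- utils::modifyList(list(n_donors = 2L, n_proteins = 150L, seed = 7L),
                            list(...))
  do.call(sim_config, args)
}

test_that("a fixed seed gives byte-identical output", {
  a <- simulate_experiment(small_cfg())
  b <- simulate_experiment(small_cfg())
  expect_identical(a, b)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_experiment(small_cfg(), out_dir = d1)
  simulate_experiment(small_cfg(), out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
  # a different seed changes the evidence
  c2 <- simulate_experiment(small_cfg(seed = 8L))
  expect_false(identical(a$runs, c2$runs))
})

test_that("adding donors does not perturb existing runs", {
  two <- simulate_experiment(small_cfg())
  three <- simulate_experiment(small_cfg(n_donors = 3L))
  expect_identical(two$runs[["D1_CTL"]], three$runs[["D1_CTL"]])
  expect_identical(two$runs[["D2_IFN"]], three$runs[["D2_IFN"]])
})

test_that("the truth table carries the configured spike structure", {
  sim <- simulate_experiment(sim_config(n_proteins = 1000L, frac_de = 0.1,
                                        n_donors = 1L, seed = 7L))
  expect_equal(length(sim$runs), 2L)
  expect_equal(sum(sim$truth$true_log2fc != 0), 100L)
  expect_equal(nrow(sim$truth), 1000L)
  # spike magnitudes honour the configured effect size
  expect_true(all(abs(sim$truth$true_log2fc[sim$truth$true_log2fc != 0]) == 2))
  # run tables are valid PSM tables with only unique-mapping peptides
  run <- sim$runs[["D1_CTL"]]
  expect_silent(validate_psm(run))
  expect_equal(anyDuplicated(unique(run[c("peptide_seq",
                                          "protein_accessions")])$peptide_seq),
               0L)
})

test_that("invalid configurations are rejected before any output", {
  expect_error(sim_config(frac_de = 1.5), "frac_de")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(peptides_min = 1), "peptides_min")
  expect_error(sim_config(log_e_fail_frac = 1), "log_e_fail_frac")
  expect_error(sim_config(dropout_scale = -1), "dropout_scale")
})

test_that("abundance-dependent dropout creates mode-unique proteins", {
  sim <- simulate_experiment(sim_config(n_proteins = 800L, seed = 3L))
  fit <- lfqpair(sim$runs)
  expect_gt(sum(fit$stats$n_ifn_only), 0)
  expect_gt(sum(fit$stats$n_ctl_only), 0)
  # mode-unique proteins sit at low abundance
  mu_acc <- fit$diffs$accession[fit$diffs$mode != "both"]
  base <- sim$truth$baseline_log2
  expect_lt(mean(base[sim$truth$accession %in% mu_acc]), mean(base))
})

test_that("null central Z-populations are close to standard normal", {
  # envelope pre-computed from 100 simulated null donor populations
  sim <- simulate_experiment(sim_config(n_proteins = 600L, frac_de = 0,
                                        seed = 31L))
  fit <- lfqpair(sim$runs)
  for (d in fit$donors) {
    z <- fit$diffs$Z[fit$diffs$donor_id == d & fit$diffs$mode == "both"]
    ks <- suppressWarnings(stats::ks.test(z, "pnorm"))$statistic
    expect_lt(ks, 0.06)
  }
})

test_that("sensitivity is monotone in the spiked effect size", {
  sens_at <- function(effect) {
    s <- c()
    for (seed in c(5L, 6L)) {
      sim <- simulate_experiment(sim_config(n_proteins = 500L, frac_de = 0.04,
                                            effect_log2fc = effect,
                                            seed = seed))
      fit <- lfqpair(sim$runs)
      s <- c(s, recovery_metrics(fit$calls, sim$truth)$sensitivity)
    }
    mean(s)
  }
  grid <- vapply(c(0.8, 2.4, 4.0), sens_at, numeric(1))
  expect_true(all(diff(grid) >= 0))
  expect_lt(grid[1], grid[3])
})

test_that("recovery metrics are exact integer arithmetic", {
  truth <- data.frame(accession = paste0("P", 1:6),
                      true_log2fc = c(2, 2, -2, 0, 0, 0))
  calls <- data.frame(accession = paste0("P", 1:6),
                      direction = c("increased", "none", "decreased",
                                    "increased", "none", "none"),
                      stringsAsFactors = FALSE)
  m <- recovery_metrics(calls, truth)
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$fdp, 1 / 3)
  expect_equal(m$n_called, 3L)

  none <- calls
  none$direction <- "none"
  m0 <- recovery_metrics(none, truth)
  expect_equal(m0$n_called, 0L)
  expect_true(is.na(m0$fdp))
  expect_equal(m0$sensitivity, 0)

  expect_error(recovery_metrics(
    data.frame(accession = "QQ", direction = "increased"), truth),
    "absent from the truth")
})
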