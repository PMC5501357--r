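quant_row <- function(acc, donor, condition, log2i) {
  data.frame(accession = acc, donor_id = donor, condition = condition,
             log2_intensity = log2i, n_distinct_peptides = 2L, n_psms = 3L,
             stringsAsFactors = FALSE)
}

test_that("paired differences and the signed-presence convention", {
  ifn <- rbind(quant_row("A", "D1", "IFN", 14.0), quant_row("B", "D1", "IFN", 12.5))
  ctl <- rbind(quant_row("A", "D1", "CTL", 11.0), quant_row("C", "D1", "CTL", 10.0))
  dd <- pair_differences(ifn, ctl)
  expect_equal(dd$mode, c("both", "ifn_only", "ctl_only"))
  expect_equal(dd$D, c(3.0, 12.5, -10.0))
  expect_error(pair_differences(quant_row("A", "D2", "IFN", 1), ctl), "donor")
  expect_error(pair_differences(ctl, ctl), "non-IFN")
})

test_that("central population statistics use the both-mode sample", {
  dd <- pair_differences(
    rbind(quant_row("A", "D1", "IFN", 10), quant_row("B", "D1", "IFN", 11),
          quant_row("C", "D1", "IFN", 13), quant_row("E", "D1", "IFN", 9)),
    rbind(quant_row("A", "D1", "CTL", 11), quant_row("B", "D1", "CTL", 11),
          quant_row("C", "D1", "CTL", 12), quant_row("F", "D1", "CTL", 8))
  )
  st <- central_stats(dd)
  expect_equal(st$central_mean, 0)   # D in {-1, 0, 1}
  expect_equal(st$central_sd, 1)
  expect_equal(st$n_central, 3L)
  expect_equal(st$n_ifn_only, 1L)
  expect_equal(st$n_ctl_only, 1L)

  flat <- dd
  flat$D[flat$mode == "both"] <- 0.5
  expect_error(central_stats(flat), "variance")
  expect_error(central_stats(dd[dd$mode != "both", ]), "insufficient data")
})

test_that("normalization is exact, idempotent at the fixed point, and affine-invariant", {
  st <- data.frame(donor_id = "D1", central_mean = 0.5, central_sd = 2.0,
                   n_central = 10L, n_ifn_only = 0L, n_ctl_only = 0L)
  dd <- data.frame(accession = "A", donor_id = "D1", mode = "both",
                   ifn_log2 = 15, ctl_log2 = 10.5, D = 4.5, Z = NA_real_,
                   stringsAsFactors = FALSE)
  expect_equal(normalize_differences(dd, st)$Z, 2.0)

  set.seed(1)
  ifn <- quant_row(sprintf("P%02d", 1:40), "D1", "IFN", rnorm(40, 12))
  ctl <- quant_row(sprintf("P%02d", 1:40), "D1", "CTL", rnorm(40, 12))
  dd <- pair_differences(ifn, ctl)
  nd <- normalize_differences(dd, central_stats(dd))
  central_z <- nd$Z[nd$mode == "both"]
  expect_lt(abs(mean(central_z)), 1e-9)
  expect_lt(abs(sd(central_z) - 1), 1e-9)

  # renormalizing an already-standard population is the identity
  nd2 <- nd
  nd2$D <- nd$Z
  renorm <- normalize_differences(nd2, central_stats(nd2))
  expect_equal(renorm$Z, nd$Z, tolerance = 1e-12)

  # Z increases strictly with D
  ord <- order(nd$D)
  expect_true(all(diff(nd$Z[ord]) > 0))

  # a global log2 shift of both conditions leaves both-mode Z unchanged
  shift_ifn <- ifn; shift_ifn$log2_intensity <- ifn$log2_intensity + 3.7
  shift_ctl <- ctl; shift_ctl$log2_intensity <- ctl$log2_intensity + 3.7
  dd_s <- pair_differences(shift_ifn, shift_ctl)
  nd_s <- normalize_differences(dd_s, central_stats(dd_s))
  expect_equal(nd_s$Z[nd_s$mode == "both"], nd$Z[nd$mode == "both"],
               tolerance = 1e-9)
})

test_that("robust central statistics use median and scaled MAD", {
  d <- c(-1, -0.5, 0, 0.5, 1, 25)  # one gross outlier
  dd <- data.frame(accession = paste0("P", 1:6), donor_id = "D1",
                   mode = "both", ifn_log2 = 10 + d, ctl_log2 = 10,
                   D = d, Z = NA_real_, stringsAsFactors = FALSE)
  st <- central_stats(dd, robust = TRUE)
  expect_equal(st$central_mean, median(d))
  expect_equal(st$central_sd, mad(d))
  expect_lt(st$central_sd, sd(d))
})

test_that("the mode partition is exhaustive and exclusive", {
  set.seed(42)
  for (i in 1:5) {
    accs <- sprintf("P%03d", 1:50)
    in_ifn <- sample(c(TRUE, FALSE), 50, TRUE, prob = c(0.8, 0.2))
    in_ctl <- sample(c(TRUE, FALSE), 50, TRUE, prob = c(0.8, 0.2))
    keep <- in_ifn | in_ctl
    dd <- pair_differences(
      quant_row(accs[in_ifn], "D1", "IFN", rnorm(sum(in_ifn), 12)),
      quant_row(accs[in_ctl], "D1", "CTL", rnorm(sum(in_ctl), 12))
    )
    expect_setequal(dd$accession, accs[keep])
    expect_equal(anyDuplicated(dd$accession), 0L)
    expect_equal(dd$mode[match(accs[in_ifn & in_ctl], dd$accession)],
                 rep("both", sum(in_ifn & in_ctl)))
    expect_equal(dd$mode[match(accs[in_ifn & !in_ctl], dd$accession)],
                 rep("ifn_only", sum(in_ifn & !in_ctl)))
  }
})
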