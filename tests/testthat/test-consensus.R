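diff_rows <- function(acc, donors, z, mode = "both", D = NULL) {
  if (is.null(D)) D <- z
  data.frame(accession = acc, donor_id = donors, mode = mode,
             ifn_log2 = NA_real_, ctl_log2 = NA_real_, D = D, Z = z,
             stringsAsFactors = FALSE)
}

test_that("per-donor qualification thresholds are inclusive and symmetric", {
  dd <- diff_rows("A", paste0("D", 1:3), c(2.0, -2.4, 1.99))
  expect_equal(qualify_pair(dd), c("up", "down", "none"))
  expect_equal(qualify_pair(dd, inclusive = FALSE), c("none", "down", "none"))
  # mode-unique rows follow the Z rule by default but can qualify always
  mu <- diff_rows("A", "D1", 0.5, mode = "ifn_only")
  expect_equal(qualify_pair(mu), "none")
  expect_equal(qualify_pair(mu, mode_unique_rule = "always"), "up")
})

test_that("three consistent donors out of five make a call, without veto", {
  donors <- paste0("D", 1:5)
  dd <- diff_rows("A", donors, c(2.5, 2.1, 3.0, -0.3, 1.0))
  call <- consensus_call(dd, donors)
  expect_equal(call$direction, "increased")
  expect_equal(call$n_qualifying, 3L)

  # detected-only-after-treatment in three donors, unchanged in one and
  # detected-only-before in one: still called increased (no veto)
  dd2 <- diff_rows("B", donors, c(9, 8.5, 10, 0, -7.5),
                   mode = c("ifn_only", "ifn_only", "ifn_only", "both",
                            "ctl_only"),
                   D = c(9, 8.5, 10, 0, -7.5))
  call2 <- consensus_call(dd2, donors)
  expect_equal(call2$direction, "increased")
  expect_equal(call2$n_qualifying, 3L)
  expect_equal(unlist(call2[paste0("display_", donors)], use.names = FALSE),
               c("IFN", "IFN", "IFN", "1.0", "CTL"))

  expect_error(consensus_call(diff_rows("A", c("D1", "D1"), c(2, 3)), donors),
               "two differences")
})

test_that("consensus matches the brute-force counting oracle", {
  donors <- paste0("D", 1:5)
  set.seed(7)
  for (i in 1:500) {
    present <- runif(5) < 0.9
    if (!any(present)) present[1] <- TRUE
    z <- round(runif(sum(present), -4, 4), 2)
    mode <- sample(c("both", "ifn_only", "ctl_only"), sum(present), TRUE,
                   prob = c(0.8, 0.1, 0.1))
    dd <- diff_rows("A", donors[present], z, mode = mode)
    got <- consensus_call(dd, donors)
    want <- oracle_consensus(z)
    expect_identical(got$direction, want$direction)
    expect_identical(got$n_qualifying, as.integer(want$n_qualifying))
  }
})

test_that("calls are invariant under donor reordering and monotone in the threshold", {
  donors <- paste0("D", 1:5)
  set.seed(11)
  z <- c(2.4, 2.2, 2.05, -0.5, 1.2)
  dd <- diff_rows("A", donors, z)
  base <- consensus_call(dd, donors)
  perm <- sample(5)
  re <- consensus_call(dd[perm, ], donors)
  expect_identical(re, base)
  # display order follows the configured donor order, not row order
  expect_identical(unlist(re[paste0("display_", donors)]),
                   unlist(base[paste0("display_", donors)]))
  # raising the threshold can only lose the call
  for (thr in c(2, 2.1, 2.3, 2.5)) {
    d <- consensus_call(dd, donors, z_threshold = thr)$direction
    if (thr > 2.05) expect_equal(d, "none") else expect_equal(d, "increased")
  }
})

test_that("display tokens reproduce the published table conventions", {
  expect_equal(fold_display(3.053, "both"), "8.3")       # 2^3.053
  expect_equal(fold_display(1.0, "both"), "2.0")
  expect_equal(fold_display(-2.0, "both", "decreased"), "4.0")
  expect_equal(fold_display(NA_real_, "ifn_only"), "IFN")
  expect_equal(fold_display(NA_real_, "ctl_only"), "CTL")
  expect_equal(fold_display(NA_real_, NA_character_), "\u2013")
})

test_that("mutually exclusive directions when min_pairs exceeds half the donors", {
  donors <- paste0("D", 1:5)
  tab <- consensus_table(rbind(
    diff_rows("UP", donors, c(2.5, 2.5, 2.5, -2.5, -2.5)),
    diff_rows("DN", donors, c(-2.5, -2.5, -3.5, 2.5, 0)),
    diff_rows("NS", donors, c(1, -1, 0, 0.5, -0.2))
  ), donors)
  expect_equal(tab$direction[match(c("UP", "DN", "NS"), tab$accession)],
               c("increased", "decreased", "none"))
  expect_true(all(tab$n_up + tab$n_down <= 5L))
})
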