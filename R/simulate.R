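# Synthetic paired label-free experiments with known ground truth.
#
# The generative model mirrors the study design being emulated: paired
# CTL/IFN runs from several donors, 21 concatenated fractions per run,
# protein abundance split across peptides with fixed ionization weights,
# logistic abundance-dependent peptide detection (which makes low-abundance
# proteins drop below the 2-peptide quantifiability rule in one condition,
# creating mode-unique proteins), and expectation-score noise at the PSM
# level. Per-pair difference noise has SD noise_sd, so a null central
# population has SD close to noise_sd and 2 SD corresponds to about a
# 3-fold intensity change at the default 0.8.

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulation configuration
#'
#' Builds and validates the configuration of [simulate_experiment()].
#' Defaults encode the emulated study conditions: 5 donor pairs, 2000
#' proteins, 10% spiked with a 2.0 log2 fold change (80% up), per-pair
#' difference noise SD 0.8 (so that 2 SD of a null central population is
#' about a 3-fold change), 2-12 peptides per protein and 21 fractions.
#'
#' @param n_donors Number of donor pairs (default 5).
#' @param n_proteins Number of proteins (default 2000).
#' @param frac_de Fraction of proteins with a true effect (default 0.1).
#' @param effect_log2fc Magnitude of the spiked log2 fold change; scalar or
#'   vector recycled over the spiked proteins (default 2).
#' @param prop_up Proportion of spiked proteins with a positive effect
#'   (default 0.8).
#' @param noise_sd SD of the per-pair log2 difference noise (default 0.8);
#'   each condition receives independent noise with SD
#'   \code{noise_sd/sqrt(2)}.
#' @param donor_sd SD of the per-donor protein abundance effect (default 1);
#'   cancels within a pair.
#' @param baseline_mean,baseline_sd Location/spread of protein baseline log2
#'   abundance (defaults 12 and 2.5).
#' @param peptides_min,peptides_max Range of peptides per protein (2-12).
#' @param n_fractions Fractions per run (default 21).
#' @param dropout_midpoint,dropout_scale Logistic detection parameters on
#'   peptide log2 abundance: detection probability
#'   \code{plogis((x - midpoint)/scale)} (defaults 3 and 0.3).
#' @param log_e_sd Spread of PSM log10 expectation scores (default 1.2).
#' @param log_e_fail_frac Fraction of PSMs whose expectation score fails the
#'   -1.5 confidence cut (default 0.03).
#' @param psm_rate Mean number of extra PSMs per detected peptide beyond the
#'   first (Poisson; default 1).
#' @param intensity_cv SD (log2 units) of multiplicative PSM intensity
#'   noise (default 0.05).
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_donors = 5L, n_proteins = 2000L, frac_de = 0.1,
                       effect_log2fc = 2, prop_up = 0.8, noise_sd = 0.8,
                       donor_sd = 1, baseline_mean = 12, baseline_sd = 2.5,
                       peptides_min = 2L, peptides_max = 12L,
                       n_fractions = 21L, dropout_midpoint = 3,
                       dropout_scale = 0.3, log_e_sd = 1.2,
                       log_e_fail_frac = 0.03, psm_rate = 1,
                       intensity_cv = 0.05, seed = 1L) {
  cfg <- list(n_donors = as.integer(n_donors),
              n_proteins = as.integer(n_proteins), frac_de = frac_de,
              effect_log2fc = effect_log2fc, prop_up = prop_up,
              noise_sd = noise_sd, donor_sd = donor_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              peptides_min = as.integer(peptides_min),
              peptides_max = as.integer(peptides_max),
              n_fractions = as.integer(n_fractions),
              dropout_midpoint = dropout_midpoint,
              dropout_scale = dropout_scale, log_e_sd = log_e_sd,
              log_e_fail_frac = log_e_fail_frac, psm_rate = psm_rate,
              intensity_cv = intensity_cv, seed = as.integer(seed))
  with(cfg, {
    if (n_donors < 1L) stop("n_donors must be >= 1")
    if (n_proteins < 1L) stop("n_proteins must be >= 1")
    if (frac_de < 0 || frac_de > 1) stop("frac_de must be in [0, 1]")
    if (any(effect_log2fc < 0)) stop("effect_log2fc is a magnitude (>= 0)")
    if (prop_up < 0 || prop_up > 1) stop("prop_up must be in [0, 1]")
    if (noise_sd <= 0) stop("noise_sd must be > 0")
    if (donor_sd < 0) stop("donor_sd must be >= 0")
    if (peptides_min < 2L || peptides_max < peptides_min) {
      stop("need peptides_min >= 2 and peptides_max >= peptides_min")
    }
    if (n_fractions < 1L) stop("n_fractions must be >= 1")
    if (dropout_scale <= 0) stop("dropout_scale must be > 0")
    if (log_e_sd <= 0) stop("log_e_sd must be > 0")
    if (log_e_fail_frac < 0 || log_e_fail_frac >= 1) {
      stop("log_e_fail_frac must be in [0, 1)")
    }
    if (psm_rate < 0) stop("psm_rate must be >= 0")
    if (intensity_cv < 0) stop("intensity_cv must be >= 0")
    if (is.na(seed)) stop("seed must be an integer")
  })
  structure(cfg, class = "sim_config")
}

# Independent run-level seed stream derived from (seed, donor, stage);
# stage 0 = protein parameters, stage per donor/condition for run noise.
derive_seed <- function(seed, donor_i, stage) {
  (abs(as.numeric(seed)) * 7919 + donor_i * 104729 + stage * 1299709) %%
    2147483647
}

# Encode an integer as an amino-acid suffix so generated peptide sequences
# are globally unique while matching the sequence alphabet.
aa_index <- function(i) {
  out <- character(length(i))
  for (k in seq_along(i)) {
    n <- i[k] - 1L
    s <- AA_LETTERS[n %% 20L + 1L]
    while (n >= 20L) {
      n <- n %/% 20L
      s <- paste0(AA_LETTERS[n %% 20L + 1L], s)
    }
    out[k] <- s
  }
  out
}

sim_protein_params <- function(cfg) {
  set.seed(derive_seed(cfg$seed, 0, 0))
  n <- cfg$n_proteins
  accession <- sprintf("SIMP%05d", seq_len(n))
  baseline <- stats::rnorm(n, cfg$baseline_mean, cfg$baseline_sd)
  n_pept <- sample(seq(cfg$peptides_min, cfg$peptides_max), n, replace = TRUE)
  true_log2fc <- numeric(n)
  n_de <- round(cfg$frac_de * n)
  if (n_de > 0L) {
    de_idx <- sample.int(n, n_de)
    magnitude <- rep_len(cfg$effect_log2fc, n_de)
    sign <- ifelse(stats::runif(n_de) < cfg$prop_up, 1, -1)
    true_log2fc[de_idx] <- sign * magnitude
  }
  # fixed per-peptide ionization weights, shared across all runs
  pept_protein <- rep(seq_len(n), n_pept)
  total_pept <- length(pept_protein)
  w_raw <- stats::rgamma(total_pept, shape = 2.5)
  w <- w_raw / rep(as.vector(rowsum(w_raw, pept_protein)), n_pept)
  core <- matrix(sample(AA_LETTERS, total_pept * 8L, replace = TRUE), ncol = 8L)
  pept_seq <- paste0(apply(core, 1L, paste0, collapse = ""),
                     aa_index(seq_len(total_pept)))
  list(accession = accession, baseline = baseline, n_pept = n_pept,
       true_log2fc = true_log2fc, pept_protein = pept_protein,
       pept_weight = w, pept_seq = pept_seq)
}

sim_run <- function(cfg, params, donor_i, condition, donor_effect) {
  cond_stage <- if (condition == "CTL") 1L else 2L
  set.seed(derive_seed(cfg$seed, donor_i, cond_stage))
  donor_id <- sprintf("D%d", donor_i)
  n <- cfg$n_proteins
  cond_noise <- stats::rnorm(n, 0, cfg$noise_sd / sqrt(2))
  effect <- if (condition == "IFN") params$true_log2fc else 0
  prot_log2 <- params$baseline + donor_effect + cond_noise + effect

  pp <- params$pept_protein
  pept_log2 <- prot_log2[pp] + log2(params$pept_weight)
  p_detect <- stats::plogis((pept_log2 - cfg$dropout_midpoint) /
                              cfg$dropout_scale)
  detected <- stats::runif(length(pp)) < p_detect
  det_idx <- which(detected)
  n_detected_pept <- tabulate(pp[det_idx], nbins = n)

  n_psm <- 1L + stats::rpois(length(det_idx), cfg$psm_rate)
  psm_pept <- rep(det_idx, n_psm)
  total_psm <- length(psm_pept)
  # split peptide intensity over its PSMs with multiplicative log2 noise
  base_int <- 2^pept_log2[psm_pept] / rep(n_psm, n_psm)
  frag_int <- base_int * 2^stats::rnorm(total_psm, 0, cfg$intensity_cv)
  offset <- 1.5 - cfg$log_e_sd * stats::qnorm((1 + cfg$log_e_fail_frac) / 2)
  log_e <- -(abs(stats::rnorm(total_psm, 0, cfg$log_e_sd)) + offset)
  psm <- data.frame(
    donor_id = donor_id,
    condition = condition,
    fraction = sample.int(cfg$n_fractions, total_psm, replace = TRUE),
    peptide_seq = params$pept_seq[psm_pept],
    charge = sample(2:4, total_psm, replace = TRUE,
                    prob = c(0.5, 0.35, 0.15)),
    protein_accessions = params$accession[pp[psm_pept]],
    peptide_log_e = log_e,
    fragment_intensity = frag_int,
    stringsAsFactors = FALSE
  )
  list(psm = psm, n_detected_pept = n_detected_pept)
}

#' Simulate a paired label-free PSM-level experiment
#'
#' Generates one PSM table per run (donor x condition) plus a ground-truth
#' table, following the generative model described in the package vignette.
#' Output is deterministic for a fixed seed; each run draws from its own
#' seed stream derived from (seed, donor, condition), so adding donors does
#' not perturb existing runs.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Optional directory; when given, the run tables
#'   (\code{psm_<donor>_<condition>.tsv}), the truth table
#'   (\code{truth.tsv}) and the resolved configuration
#'   (\code{sim_config.dcf}) are written there.
#' @return A list with \code{runs} (named list of PSM data frames, names
#'   \code{"<donor>_<condition>"}), \code{truth} (data frame with
#'   \code{accession}, \code{true_log2fc}, \code{baseline_log2},
#'   \code{n_peptides}, and per-run detected flags
#'   \code{detected_<donor>_<condition>} marking >= 2 detected peptides),
#'   and \code{config}.
#' @export
simulate_experiment <- function(config, out_dir = NULL) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  params <- sim_protein_params(config)
  runs <- list()
  truth <- data.frame(accession = params$accession,
                      true_log2fc = params$true_log2fc,
                      baseline_log2 = params$baseline,
                      n_peptides = params$n_pept,
                      stringsAsFactors = FALSE)
  for (donor_i in seq_len(config$n_donors)) {
    set.seed(derive_seed(config$seed, donor_i, 3L))
    donor_effect <- stats::rnorm(config$n_proteins, 0, config$donor_sd)
    for (condition in c("CTL", "IFN")) {
      run <- sim_run(config, params, donor_i, condition, donor_effect)
      key <- sprintf("D%d_%s", donor_i, condition)
      runs[[key]] <- run$psm
      truth[[paste0("detected_", key)]] <- run$n_detected_pept >= 2L
    }
  }
  out <- list(runs = runs, truth = truth, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (key in names(runs)) {
      write_psm_table(runs[[key]], file.path(out_dir,
                                             paste0("psm_", key, ".tsv")))
    }
    write_tsv(truth, file.path(out_dir, "truth.tsv"))
    write.dcf(data.frame(unclass(config)), file.path(out_dir, "sim_config.dcf"))
  }
  out
}

#' Recovery metrics against simulation ground truth
#'
#' Compares a consensus table with the generator's truth: sensitivity is the
#' fraction of truly changed proteins called in the correct direction, and
#' the false-discovery proportion (FDP) is the fraction of called proteins
#' that are truly null. All counts are exact integer arithmetic.
#'
#' @param calls A consensus data frame with \code{accession} and
#'   \code{direction}.
#' @param truth A truth data frame with \code{accession} and
#'   \code{true_log2fc}.
#' @return A list: \code{sensitivity}, \code{fdp} (\code{NA} when nothing is
#'   called), \code{n_called}, and a 3x3 \code{confusion} table of truth
#'   direction vs called direction.
#' @export
recovery_metrics <- function(calls, truth) {
  if (!all(calls$accession %in% truth$accession)) {
    stop("calls contain accessions absent from the truth table")
  }
  direction <- calls$direction[match(truth$accession, calls$accession)]
  direction[is.na(direction)] <- "none"
  truth_dir <- ifelse(truth$true_log2fc > 0, "increased",
                      ifelse(truth$true_log2fc < 0, "decreased", "null"))
  called <- direction != "none"
  n_true <- sum(truth_dir != "null")
  n_correct <- sum(called & direction == truth_dir)
  n_called <- sum(called)
  n_false <- sum(called & truth_dir == "null")
  confusion <- table(truth = factor(truth_dir,
                                    c("increased", "decreased", "null")),
                     called = factor(direction,
                                     c("increased", "decreased", "none")))
  list(sensitivity = if (n_true > 0L) n_correct / n_true else NA_real_,
       fdp = if (n_called > 0L) n_false / n_called else NA_real_,
       n_called = n_called, confusion = confusion)
}
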