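# Shared fixture builders and independent brute-force oracles.

make_psm <- function(peptide, accessions, log_e = -2, intensity = 1000,
                     donor = "D1", condition = "CTL", fraction = 1L,
                     charge = 2L) {
  data.frame(donor_id = donor, condition = condition,
             fraction = as.integer(fraction), peptide_seq = peptide,
             charge = as.integer(charge), protein_accessions = accessions,
             peptide_log_e = log_e, fragment_intensity = intensity,
             stringsAsFactors = FALSE)
}

rbind_psm <- function(...) do.call(rbind, list(...))

# Brute-force unique-peptide oracle: a peptide is unique iff the union of
# accession lists over all of its PSMs has exactly one element.
oracle_unique_peptides <- function(psm) {
  out <- list()
  for (pept in unique(psm$peptide_seq)) {
    rows <- psm[psm$peptide_seq == pept, ]
    accs <- unique(unlist(strsplit(rows$protein_accessions, ";", fixed = TRUE)))
    if (length(accs) == 1L) out[[pept]] <- accs
  }
  out
}

# Brute-force consensus oracle: plain counting of the "at least min_pairs
# donors with |Z| >= z in the same direction, no veto" rule.
oracle_consensus <- function(z, min_pairs = 3L, z_threshold = 2) {
  n_up <- sum(z >= z_threshold, na.rm = TRUE)
  n_down <- sum(z <= -z_threshold, na.rm = TRUE)
  if (n_up >= min_pairs) {
    list(direction = "increased", n_qualifying = n_up)
  } else if (n_down >= min_pairs) {
    list(direction = "decreased", n_qualifying = n_down)
  } else {
    list(direction = "none", n_qualifying = 0L)
  }
}

# Random PSM run with shared and unique peptides, for property tests.
random_run <- function(seed, n_prot = 6L, donor = "D1", condition = "CTL") {
  set.seed(seed)
  accs <- paste0("ACC", seq_len(n_prot))
  rows <- list()
  for (i in seq_len(30L)) {
    n_map <- sample(c(1L, 1L, 1L, 2L), 1L)
    target <- sample(accs, n_map)
    pept <- paste0(paste(sample(c("A", "G", "L", "S", "V"), 8L, TRUE),
                         collapse = ""), "K")
    n_psm <- sample(1:3, 1L)
    for (k in seq_len(n_psm)) {
      rows[[length(rows) + 1L]] <- make_psm(
        pept, paste(target, collapse = ";"),
        log_e = round(stats::runif(1L, -4, 0), 2L),
        intensity = round(stats::runif(1L, 10, 5000), 1L),
        donor = donor, condition = condition,
        fraction = sample(1:21, 1L))
    }
  }
  do.call(rbind, rows)
}
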