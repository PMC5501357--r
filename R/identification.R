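# Confident-identification and quantifiability rules.
#
# A peptide is "unique" (proteotypic) within a run iff the union of the
# accession lists over all of its PSMs in that run is a single accession.
# Shared peptides contribute spectra to every listed protein but never count
# towards a protein's distinct unique peptides, and their intensity is
# excluded from quantitation to avoid double counting.

#' Split semicolon-separated accession lists
#' @noRd
split_accessions <- function(x) strsplit(x, ";", fixed = TRUE)

# Per-peptide accession union for a run; returns a named integer vector of
# the number of distinct accessions each peptide sequence maps to, plus the
# single accession for unique peptides.
peptide_uniqueness <- function(psm) {
  accs <- split_accessions(psm$protein_accessions)
  long <- data.frame(
    peptide = rep(psm$peptide_seq, lengths(accs)),
    accession = unlist(accs, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  long <- long[!duplicated(paste(long$peptide, long$accession, sep = "\r")), ,
               drop = FALSE]
  n_acc <- table(long$peptide)
  unique_pept <- names(n_acc)[n_acc == 1L]
  acc_of <- long$accession[match(unique_pept, long$peptide)]
  names(acc_of) <- unique_pept
  list(long = long, n_accessions = n_acc, unique_accession = acc_of)
}

#' Group PSMs into per-protein evidence with unique-peptide assignment
#'
#' For every accession appearing in a run's PSM table, collects the PSMs that
#' list it and determines which of its peptide sequences are unique to it
#' (map to exactly one accession across the whole run). Uniqueness is
#' evaluated per run against the accessions observed in that run, on stripped
#' sequences.
#'
#' @param psm A validated PSM data frame for one run.
#' @param protein_log_e Optional named numeric vector of protein-level
#'   log10 expectation scores (names = accessions). Accessions without an
#'   entry get \code{NA} (score unavailable).
#' @return A named list of \code{protein_evidence} objects, sorted by
#'   accession. Each holds \code{accession}, \code{psm} (the PSM rows listing
#'   this protein), \code{unique_peptides}, and \code{protein_log_e}.
#' @export
assign_uniqueness <- function(psm, protein_log_e = NULL) {
  psm <- validate_psm(psm)
  if (nrow(psm) == 0L) return(structure(list(), names = character()))
  accs <- split_accessions(psm$protein_accessions)
  uniq <- peptide_uniqueness(psm)
  row_of_acc <- split(rep(seq_len(nrow(psm)), lengths(accs)),
                      unlist(accs, use.names = FALSE))
  acc_names <- sort(names(row_of_acc))
  out <- lapply(acc_names, function(a) {
    rows <- psm[row_of_acc[[a]], , drop = FALSE]
    upept <- names(uniq$unique_accession)[uniq$unique_accession == a]
    upept <- intersect(upept, rows$peptide_seq)
    ple <- NA_real_
    if (!is.null(protein_log_e) && a %in% names(protein_log_e)) {
      ple <- unname(protein_log_e[[a]])
    }
    structure(list(accession = a, psm = rows, unique_peptides = upept,
                   protein_log_e = ple),
              class = "protein_evidence")
  })
  names(out) <- acc_names
  out
}

#' @export
print.protein_evidence <- function(x, ...) {
  cat("Protein evidence for", x$accession, "\n")
  cat("  PSMs:", nrow(x$psm), " distinct unique peptides:",
      length(x$unique_peptides), "\n")
  if (!is.na(x$protein_log_e)) cat("  protein log(e):", x$protein_log_e, "\n")
  invisible(x)
}

# Distinct unique peptides having at least one PSM at or below the peptide
# expectation threshold.
confident_unique_peptides <- function(evidence, peptide_log_e_max) {
  psm <- evidence$psm
  keep <- psm$peptide_seq %in% evidence$unique_peptides &
    psm$peptide_log_e <= peptide_log_e_max
  unique(psm$peptide_seq[keep])
}

#' Confident-identification filter
#'
#' A protein passes when at least \code{min_unique_peptides} distinct unique
#' peptide sequences each have a PSM with log10 expectation at or below
#' \code{peptide_log_e_max}, and its protein-level score (when available) is
#' at or below \code{protein_log_e_max}. Both thresholds are inclusive
#' ("or lower"). When no protein-level score is supplied the protein clause
#' is vacuously satisfied, so minimal PSM tables remain usable.
#'
#' @param evidence A \code{protein_evidence} object from
#'   [assign_uniqueness()].
#' @param peptide_log_e_max Peptide log10 expectation cut-off (default -1.5).
#' @param protein_log_e_max Protein log10 expectation cut-off (default -3).
#' @param min_unique_peptides Minimum distinct unique peptides (default 2).
#' @return \code{TRUE} or \code{FALSE}.
#' @export
filter_confident <- function(evidence, peptide_log_e_max = -1.5,
                             protein_log_e_max = -3,
                             min_unique_peptides = 2L) {
  stopifnot(is.finite(peptide_log_e_max), is.finite(protein_log_e_max))
  n_conf <- length(confident_unique_peptides(evidence, peptide_log_e_max))
  pep_ok <- n_conf >= min_unique_peptides
  prot_ok <- is.na(evidence$protein_log_e) ||
    evidence$protein_log_e <= protein_log_e_max
  pep_ok && prot_ok
}

#' Quantifiability rule
#'
#' A protein is quantifiable in a run when at least
#' \code{min_unique_peptides} distinct (non-redundant) unique peptide
#' sequences are confidently detected there. Sequences, not spectra, are
#' counted: one peptide observed in ten spectra still counts once.
#'
#' @inheritParams filter_confident
#' @return \code{TRUE} or \code{FALSE}.
#' @export
quantifiable <- function(evidence, peptide_log_e_max = -1.5,
                         min_unique_peptides = 2L) {
  length(confident_unique_peptides(evidence, peptide_log_e_max)) >=
    min_unique_peptides
}
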