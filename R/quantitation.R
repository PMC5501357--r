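# Label-free protein quantitation: per-run protein expression is the log2 of
# the summed MS/MS fragment intensities of the protein's confidently
# identified unique peptides. Natural intensities are summed first, then
# logged.

#' Protein expression from summed fragment intensities
#'
#' Sums the fragment intensities of every confident PSM (peptide log10
#' expectation at or below the threshold) of the protein's unique peptides
#' and maps the sum to log2. Shared-peptide intensity never contributes.
#'
#' @param evidence A \code{protein_evidence} object.
#' @param peptide_log_e_max Peptide log10 expectation cut-off (default -1.5).
#' @param min_unique_peptides Minimum distinct unique peptides (default 2).
#' @return A one-row data frame with \code{accession}, \code{donor_id},
#'   \code{condition}, \code{log2_intensity}, \code{n_distinct_peptides},
#'   \code{n_psms}.
#' @export
protein_log2_intensity <- function(evidence, peptide_log_e_max = -1.5,
                                   min_unique_peptides = 2L) {
  if (!quantifiable(evidence, peptide_log_e_max, min_unique_peptides)) {
    stop("protein ", evidence$accession,
         " is not quantifiable (needs >= ", min_unique_peptides,
         " confident unique peptides)")
  }
  psm <- evidence$psm
  conf_pept <- confident_unique_peptides(evidence, peptide_log_e_max)
  keep <- psm$peptide_seq %in% conf_pept & psm$peptide_log_e <= peptide_log_e_max
  s <- sum(psm$fragment_intensity[keep])
  if (!is.finite(s) || s <= 0) {
    stop("degenerate intensity sum (", s, ") for protein ", evidence$accession)
  }
  data.frame(
    accession = evidence$accession,
    donor_id = psm$donor_id[1L],
    condition = psm$condition[1L],
    log2_intensity = log2(s),
    n_distinct_peptides = length(conf_pept),
    n_psms = sum(keep),
    stringsAsFactors = FALSE
  )
}

#' Quantify every confidently identified protein in a run
#'
#' Applies the unique-peptide assignment, the confident-identification
#' filter, and the quantifiability rule, then rolls confident unique-peptide
#' fragment intensities up to log2 protein expression values. The
#' implementation is a vectorised equivalent of composing
#' [assign_uniqueness()], [filter_confident()], [quantifiable()] and
#' [protein_log2_intensity()] protein by protein.
#'
#' @param run A validated PSM data frame for one run (one donor, one
#'   condition, fractions already merged).
#' @param peptide_log_e_max Peptide log10 expectation cut-off (default -1.5).
#' @param protein_log_e_max Protein log10 expectation cut-off (default -3);
#'   applied only to accessions present in \code{protein_log_e}.
#' @param min_unique_peptides Minimum distinct unique peptides (default 2).
#' @param protein_log_e Optional named numeric vector of protein-level log10
#'   expectation scores.
#' @return A data frame of per-protein quantifications, accession-sorted.
#'   Proteins with a non-positive intensity sum are dropped with a warning.
#' @export
quantify_run <- function(run, peptide_log_e_max = -1.5,
                         protein_log_e_max = -3, min_unique_peptides = 2L,
                         protein_log_e = NULL) {
  run <- validate_psm(run)
  empty <- data.frame(accession = character(), donor_id = character(),
                      condition = character(), log2_intensity = double(),
                      n_distinct_peptides = integer(), n_psms = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(run) == 0L) return(empty)
  donor <- unique(run$donor_id)
  cond <- unique(run$condition)
  if (length(donor) != 1L || length(cond) != 1L) {
    stop("quantify_run expects a single run (one donor, one condition); got ",
         length(donor), " donor(s) and ", length(cond), " condition(s)")
  }

  uniq <- peptide_uniqueness(run)
  acc_of_pept <- uniq$unique_accession
  keep <- run$peptide_seq %in% names(acc_of_pept) &
    run$peptide_log_e <= peptide_log_e_max
  if (!any(keep)) return(empty)
  pept <- run$peptide_seq[keep]
  acc <- unname(acc_of_pept[pept])
  intensity <- run$fragment_intensity[keep]

  pair_key <- !duplicated(paste(acc, pept, sep = "\r"))
  n_pept <- table(acc[pair_key])
  ok_acc <- names(n_pept)[n_pept >= min_unique_peptides]
  if (!is.null(protein_log_e)) {
    scored <- intersect(ok_acc, names(protein_log_e))
    fail <- scored[!is.na(protein_log_e[scored]) &
                     protein_log_e[scored] > protein_log_e_max]
    ok_acc <- setdiff(ok_acc, fail)
  }
  if (length(ok_acc) == 0L) return(empty)

  sel <- acc %in% ok_acc
  acc_f <- factor(acc[sel], levels = sort(ok_acc))
  sums <- as.vector(rowsum(intensity[sel], acc_f))
  n_psms <- as.vector(table(acc_f))
  out <- data.frame(
    accession = sort(ok_acc),
    donor_id = donor,
    condition = cond,
    log2_intensity = log2(sums),
    n_distinct_peptides = as.integer(n_pept[sort(ok_acc)]),
    n_psms = n_psms,
    stringsAsFactors = FALSE
  )
  bad <- !is.finite(out$log2_intensity)
  if (any(bad)) {
    warning("dropping ", sum(bad), " protein(s) with degenerate intensity sum")
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
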