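# Paired differential analysis. For each donor, D = log2(IFN) - log2(CTL)
# for proteins quantified in both conditions; proteins quantifiable in only
# one condition form the two outer populations and carry the signed log2
# intensity of the observed mode as their difference. All three populations
# are put on a common scale by normalising with the central (both-mode)
# population's mean and SD.

#' Per-donor paired log2 differences
#'
#' Joins the IFN and CTL quantifications of one donor on accession and
#' assigns each protein its population mode: \code{both} (quantified in both
#' conditions, \code{D = ifn_log2 - ctl_log2}), \code{ifn_only}
#' (\code{D = +ifn_log2}) or \code{ctl_only} (\code{D = -ctl_log2}). The
#' signed-presence convention places mode-unique proteins in outer
#' populations flanking the central one, since detected proteins have large
#' positive log2 intensities. A protein quantifiable in neither condition is
#' simply absent (no imputation).
#'
#' @param ifn,ctl Per-run quantification data frames from [quantify_run()]
#'   for the same donor, conditions \code{"IFN"} and \code{"CTL"}.
#' @return A data frame with \code{accession}, \code{donor_id}, \code{mode},
#'   \code{ifn_log2}, \code{ctl_log2}, \code{D} and \code{Z} (\code{NA}
#'   until [normalize_differences()] is applied), accession-sorted.
#' @export
pair_differences <- function(ifn, ctl) {
  if (nrow(ifn) > 0L && any(ifn$condition != "IFN")) {
    stop("'ifn' quantification table contains non-IFN rows")
  }
  if (nrow(ctl) > 0L && any(ctl$condition != "CTL")) {
    stop("'ctl' quantification table contains non-CTL rows")
  }
  donors <- unique(c(ifn$donor_id, ctl$donor_id))
  if (length(donors) > 1L) {
    stop("donor mismatch between conditions: ",
         paste(donors, collapse = ", "))
  }
  if (length(donors) == 0L) donors <- NA_character_
  if (anyDuplicated(ifn$accession) || anyDuplicated(ctl$accession)) {
    stop("duplicated accession within a quantification table")
  }
  acc <- sort(union(ifn$accession, ctl$accession))
  ifn_log2 <- ifn$log2_intensity[match(acc, ifn$accession)]
  ctl_log2 <- ctl$log2_intensity[match(acc, ctl$accession)]
  mode <- ifelse(!is.na(ifn_log2) & !is.na(ctl_log2), "both",
                 ifelse(!is.na(ifn_log2), "ifn_only", "ctl_only"))
  d <- ifelse(mode == "both", ifn_log2 - ctl_log2,
              ifelse(mode == "ifn_only", ifn_log2, -ctl_log2))
  data.frame(accession = acc, donor_id = donors, mode = mode,
             ifn_log2 = ifn_log2, ctl_log2 = ctl_log2, D = d, Z = NA_real_,
             stringsAsFactors = FALSE)
}

#' Central-population location and scale
#'
#' Estimates the mean and SD of the central difference population (proteins
#' observed in both conditions) of one donor pair. By default the sample
#' mean and sample SD (n-1 denominator) are used; the robust alternative
#' uses the median and the scaled MAD.
#'
#' @param diffs A per-donor difference data frame from [pair_differences()].
#' @param robust Use median/MAD instead of mean/SD (default \code{FALSE}).
#' @return A one-row data frame: \code{donor_id}, \code{central_mean},
#'   \code{central_sd}, \code{n_central}, \code{n_ifn_only},
#'   \code{n_ctl_only}.
#' @export
central_stats <- function(diffs, robust = FALSE) {
  central <- diffs$D[diffs$mode == "both"]
  if (length(central) < 2L) {
    stop("insufficient data: need >= 2 both-mode proteins to estimate the ",
         "central population (got ", length(central), ")")
  }
  if (robust) {
    m <- stats::median(central)
    s <- stats::mad(central)
  } else {
    m <- mean(central)
    s <- stats::sd(central)
  }
  if (!is.finite(s) || s <= 0) {
    stop("insufficient variance in the central population (SD = ", s, ")")
  }
  data.frame(donor_id = diffs$donor_id[1L], central_mean = m, central_sd = s,
             n_central = length(central),
             n_ifn_only = sum(diffs$mode == "ifn_only"),
             n_ctl_only = sum(diffs$mode == "ctl_only"),
             stringsAsFactors = FALSE)
}

#' Normalise all three difference populations by the central one
#'
#' Applies \code{Z = (D - central_mean) / central_sd} to every difference of
#' the donor pair, regardless of mode. After normalisation the central
#' population has sample mean 0 and sample SD 1 exactly (when the default
#' mean/SD statistics produced \code{stats}); the outer populations are on
#' the same scale, which makes the cross-donor comparison possible, though
#' their Z-scores are not probability calibrated.
#'
#' @param diffs A per-donor difference data frame.
#' @param stats A one-row stats data frame from [central_stats()] for the
#'   same donor.
#' @return \code{diffs} with the \code{Z} column filled.
#' @export
normalize_differences <- function(diffs, stats) {
  if (nrow(stats) != 1L) stop("'stats' must be a single-donor summary")
  if (!is.na(stats$donor_id) && nrow(diffs) > 0L &&
      any(diffs$donor_id != stats$donor_id)) {
    stop("donor mismatch between differences and population stats")
  }
  if (!is.finite(stats$central_sd) || stats$central_sd <= 0) {
    stop("central_sd must be positive")
  }
  diffs$Z <- (diffs$D - stats$central_mean) / stats$central_sd
  diffs
}
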