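# Canonical column order of a PSM evidence table.
PSM_COLUMNS <- c("donor_id", "condition", "fraction", "peptide_seq", "charge",
                 "protein_accessions", "peptide_log_e", "fragment_intensity")

AA_REGEX <- "^[ACDEFGHIKLMNPQRSTVWY]+$"

#' Validate a PSM evidence table
#'
#' Checks that a data frame of peptide-spectrum matches satisfies the
#' structural invariants the pipeline relies on: plain amino-acid peptide
#' sequences, conditions restricted to \code{"CTL"}/\code{"IFN"}, non-negative
#' finite fragment intensities, and a non-empty semicolon-separated accession
#' list on every row.
#'
#' @param psm A data frame with columns \code{donor_id}, \code{condition},
#'   \code{fraction}, \code{peptide_seq}, \code{charge},
#'   \code{protein_accessions}, \code{peptide_log_e},
#'   \code{fragment_intensity}.
#' @return The validated data frame, invisibly coerced to canonical column
#'   types (character ids, integer fraction/charge, double scores).
#' @export
validate_psm <- function(psm) {
  if (!is.data.frame(psm)) stop("PSM table must be a data frame")
  missing_cols <- setdiff(PSM_COLUMNS, names(psm))
  if (length(missing_cols) > 0L) {
    stop("PSM table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  psm <- psm[PSM_COLUMNS]
  psm$donor_id <- as.character(psm$donor_id)
  psm$condition <- as.character(psm$condition)
  psm$peptide_seq <- as.character(psm$peptide_seq)
  psm$protein_accessions <- as.character(psm$protein_accessions)
  psm$fraction <- as.integer(psm$fraction)
  psm$charge <- as.integer(psm$charge)
  psm$peptide_log_e <- as.double(psm$peptide_log_e)
  psm$fragment_intensity <- as.double(psm$fragment_intensity)

  bad <- which(!psm$condition %in% c("CTL", "IFN"))
  if (length(bad) > 0L) {
    stop("invalid condition (must be CTL or IFN) in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  bad <- which(!grepl(AA_REGEX, psm$peptide_seq))
  if (length(bad) > 0L) {
    stop("peptide_seq contains non amino-acid characters in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  bad <- which(!is.finite(psm$fragment_intensity) | psm$fragment_intensity < 0)
  if (length(bad) > 0L) {
    stop("fragment_intensity must be finite and >= 0; offending row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  accs <- strsplit(psm$protein_accessions, ";", fixed = TRUE)
  bad <- which(vapply(accs, function(a) length(a) == 0L || any(!nzchar(a)),
                      logical(1L)))
  if (length(bad) > 0L) {
    stop("empty protein accession list in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  bad <- which(is.na(psm$fraction) | psm$fraction < 0L)
  if (length(bad) > 0L) {
    stop("fraction must be a non-negative integer (0 = pre-merged); row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  invisible(psm)
}

#' Read a PSM evidence table from a tab-separated file
#'
#' The canonical on-disk format is a UTF-8 TSV with a header row naming the
#' eight PSM fields; protein accessions are semicolon-separated within their
#' column. Row order is preserved. Parse failures are reported with the
#' offending file line number (header is line 1).
#'
#' @param path Path to the TSV file.
#' @return A validated PSM data frame, one row per peptide-spectrum match.
#' @seealso [write_psm_table()]
#' @export
read_psm_table <- function(path) {
  if (!file.exists(path)) stop("PSM table not found: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = TRUE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(PSM_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("PSM table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw <- raw[PSM_COLUMNS]
  numeric_field <- function(x, name) {
    val <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(val) & !is.na(x) & nzchar(x))
    if (length(bad) > 0L) {
      stop("non-numeric ", name, " at line ", bad[1L] + 1L, " of ", path,
           " (value '", x[bad[1L]], "')")
    }
    if (anyNA(val)) {
      stop("missing ", name, " at line ", which(is.na(val))[1L] + 1L, " of ", path)
    }
    val
  }
  raw$fraction <- as.integer(numeric_field(raw$fraction, "fraction"))
  raw$charge <- as.integer(numeric_field(raw$charge, "charge"))
  raw$peptide_log_e <- numeric_field(raw$peptide_log_e, "peptide_log_e")
  raw$fragment_intensity <- numeric_field(raw$fragment_intensity,
                                          "fragment_intensity")
  validate_psm(raw)
}

#' Write a PSM evidence table to a tab-separated file
#'
#' @param psm A PSM data frame (validated on the way out).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_psm_table <- function(psm, path) {
  psm <- validate_psm(psm)
  utils::write.table(psm, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Merge per-fraction PSM tables into a single run
#'
#' A run is the concatenation of its fraction files: high-pH fractionation
#' partitions the evidence but each PSM remains an independent observation,
#' so merging is pure concatenation with no spectrum-level de-duplication.
#' Record count and total fragment intensity are conserved.
#'
#' @param tables A list of PSM data frames (one per fraction), or a single
#'   data frame for pre-merged input.
#' @param donor_id Donor label the merged run must belong to.
#' @param condition \code{"CTL"} or \code{"IFN"}.
#' @return A PSM data frame containing all input rows in input order, with
#'   attributes \code{donor_id} and \code{condition}.
#' @export
merge_fractions <- function(tables, donor_id, condition) {
  if (is.data.frame(tables)) tables <- list(tables)
  stopifnot(length(condition) == 1L, length(donor_id) == 1L)
  tables <- lapply(tables, validate_psm)
  run <- do.call(rbind, c(tables, list(make.row.names = FALSE)))
  if (is.null(run)) run <- empty_psm_table()
  if (nrow(run) > 0L) {
    if (any(run$donor_id != donor_id)) {
      stop("fraction table contains records for a different donor than '",
           donor_id, "'")
    }
    if (any(run$condition != condition)) {
      stop("fraction table contains records for a different condition than '",
           condition, "'")
    }
  }
  attr(run, "donor_id") <- as.character(donor_id)
  attr(run, "condition") <- as.character(condition)
  run
}

empty_psm_table <- function() {
  data.frame(donor_id = character(), condition = character(),
             fraction = integer(), peptide_seq = character(),
             charge = integer(), protein_accessions = character(),
             peptide_log_e = double(), fragment_intensity = double(),
             stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = TRUE,
                    fileEncoding = "UTF-8")
}
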