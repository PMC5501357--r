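# Downstream annotation of consensus calls: membrane/secreted classification
# from a local transmembrane (TM) / signal-peptide (SP) table, and
# transcript-level interferon responsiveness from a local fold-change table.
# Annotation tables are always consumed from local TSVs, never fetched live.

#' Read a TM/SP annotation table
#'
#' Expected columns: \code{accession}, \code{gene}, \code{tm} (0/1),
#' \code{sp} (0/1). Extra columns are kept.
#'
#' @param path Path to a TSV file.
#' @return A data frame with \code{tm}/\code{sp} as logical.
#' @export
read_annotation_table <- function(path) {
  ann <- read_tsv(path)
  need <- c("accession", "gene", "tm", "sp")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols) > 0L) {
    stop("annotation table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ann$tm <- as.logical(as.integer(ann$tm))
  ann$sp <- as.logical(as.integer(ann$sp))
  if (anyNA(ann$tm) || anyNA(ann$sp)) stop("tm/sp must be 0 or 1")
  if (anyDuplicated(ann$accession)) stop("duplicated accession in annotation table")
  ann
}

#' Read a transcript-response table
#'
#' Expected columns: \code{accession}, \code{max_abs_fold} (largest absolute
#' transcript fold change reported under IFN-γ treatment; >= 1).
#'
#' @param path Path to a TSV file.
#' @return A validated data frame.
#' @export
read_transcript_table <- function(path) {
  tab <- read_tsv(path)
  need <- c("accession", "max_abs_fold")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop("transcript table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab$max_abs_fold <- as.numeric(tab$max_abs_fold)
  if (any(!is.finite(tab$max_abs_fold) | tab$max_abs_fold < 1)) {
    stop("max_abs_fold must be finite and >= 1")
  }
  tab
}

#' Classify called proteins as membrane, secreted or other
#'
#' Membrane proteins are those with a predicted transmembrane region
#' (\code{tm}); secreted proteins lack a transmembrane region but carry a
#' signal peptide (\code{!tm & sp}); the remainder of annotated proteins are
#' \code{other}, and proteins absent from the annotation table are
#' \code{unannotated}. The four categories partition the calls.
#'
#' @param calls A data frame with at least an \code{accession} column
#'   (typically a consensus table).
#' @param annotations An annotation data frame from
#'   [read_annotation_table()].
#' @return \code{calls} with \code{gene} and \code{category} columns added.
#' @export
classify_membrane_secreted <- function(calls, annotations) {
  i <- match(calls$accession, annotations$accession)
  tm <- annotations$tm[i]
  sp <- annotations$sp[i]
  calls$gene <- annotations$gene[i]
  calls$category <- ifelse(is.na(i), "unannotated",
                           ifelse(tm, "membrane",
                                  ifelse(sp, "secreted", "other")))
  calls
}

#' Flag transcript-level interferon responsiveness
#'
#' A protein is flagged responsive when its accession appears in the
#' transcript-response table with an absolute fold change of at least
#' \code{min_fold} (inclusive); accessions absent from the table or below
#' the threshold are not-reported.
#'
#' @param calls A data frame with an \code{accession} column.
#' @param table A transcript-response data frame from
#'   [read_transcript_table()].
#' @param min_fold Minimum absolute transcript fold change (default 2).
#' @return \code{calls} with a logical \code{transcript_responsive} column.
#' @export
crossref_transcript_response <- function(calls, table, min_fold = 2) {
  i <- match(calls$accession, table$accession)
  fold <- table$max_abs_fold[i]
  calls$transcript_responsive <- !is.na(fold) & fold >= min_fold
  calls
}
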