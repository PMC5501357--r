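# The central fitting surface: lfqpair() takes per-run PSM evidence for a
# paired design and returns a classed object holding every intermediate of
# the analysis (per-run quantifications, per-donor differences and central
# population statistics, cross-donor consensus calls).

#' Fit a paired label-free differential analysis
#'
#' Runs the full analysis on PSM-level evidence: per-run confident
#' identification and unique-peptide quantitation, per-donor paired log2
#' differences partitioned into the three populations (both / IFN-only /
#' CTL-only), central-population normalisation, and the cross-donor
#' consensus call (at least \code{min_pairs} donors changed by at least
#' \code{z_threshold} central-population SDs in the same direction; no
#' veto from discordant donors).
#'
#' @param runs Either a named list of PSM data frames (names
#'   \code{"<donor>_<condition>"}) or a single PSM data frame containing all
#'   runs, which is split on (\code{donor_id}, \code{condition}).
#' @param donors Character vector fixing donor order; defaults to the order
#'   of first appearance.
#' @param peptide_log_e_max Peptide log10 expectation cut-off (default -1.5).
#' @param protein_log_e_max Protein log10 expectation cut-off (default -3).
#' @param min_unique_peptides Minimum distinct unique peptides per protein
#'   and run (default 2).
#' @param z_threshold Per-donor qualification threshold in SD units
#'   (default 2).
#' @param min_pairs Minimum consistent donors for a consensus call
#'   (default 3).
#' @param robust_sd Normalise with median/MAD instead of mean/SD
#'   (default \code{FALSE}).
#' @param mode_unique_rule How mode-unique proteins qualify:
#'   \code{"zscore"} (common-scale Z, default) or \code{"always"}.
#' @param inclusive Treat \code{z_threshold} as inclusive (default
#'   \code{TRUE}).
#' @param protein_log_e Optional named numeric vector of protein-level log10
#'   expectation scores applied in every run.
#' @return An object of class \code{"lfqpair"}: a list with \code{quant}
#'   (all per-run quantifications), \code{diffs} (all normalised per-donor
#'   differences), \code{stats} (per-donor central-population statistics),
#'   \code{calls} (consensus table), \code{donors} and \code{params}.
#' @examples
#' sim <- simulate_experiment(sim_config(n_donors = 3, n_proteins = 120,
#'                                       seed = 42))
#' fit <- lfqpair(sim$runs)
#' print(fit)
#' head(coef(fit))
#' @export
lfqpair <- function(runs, donors = NULL, peptide_log_e_max = -1.5,
                    protein_log_e_max = -3, min_unique_peptides = 2L,
                    z_threshold = 2, min_pairs = 3L, robust_sd = FALSE,
                    mode_unique_rule = c("zscore", "always"),
                    inclusive = TRUE, protein_log_e = NULL) {
  mode_unique_rule <- match.arg(mode_unique_rule)
  if (is.data.frame(runs)) {
    runs <- validate_psm(runs)
    runs <- split(runs, paste(runs$donor_id, runs$condition, sep = "_"))
  }
  if (length(runs) == 0L) stop("no runs supplied")
  run_donor <- vapply(runs, function(r) unique(r$donor_id)[1L], character(1L))
  run_cond <- vapply(runs, function(r) unique(r$condition)[1L], character(1L))
  if (is.null(donors)) donors <- unique(run_donor)
  for (d in donors) {
    if (sum(run_donor == d & run_cond == "CTL") != 1L ||
        sum(run_donor == d & run_cond == "IFN") != 1L) {
      stop("donor ", d, " must have exactly one CTL and one IFN run")
    }
  }
  quant <- list()
  diffs <- list()
  stats_rows <- list()
  for (d in donors) {
    ctl <- quantify_run(runs[[which(run_donor == d & run_cond == "CTL")]],
                        peptide_log_e_max, protein_log_e_max,
                        min_unique_peptides, protein_log_e)
    ifn <- quantify_run(runs[[which(run_donor == d & run_cond == "IFN")]],
                        peptide_log_e_max, protein_log_e_max,
                        min_unique_peptides, protein_log_e)
    dd <- pair_differences(ifn, ctl)
    st <- central_stats(dd, robust = robust_sd)
    dd <- normalize_differences(dd, st)
    quant[[d]] <- rbind(ctl, ifn)
    diffs[[d]] <- dd
    stats_rows[[d]] <- st
  }
  all_diffs <- do.call(rbind, c(diffs, list(make.row.names = FALSE)))
  calls <- consensus_table(all_diffs, donors = donors, min_pairs = min_pairs,
                           z_threshold = z_threshold, inclusive = inclusive,
                           mode_unique_rule = mode_unique_rule)
  structure(list(
    quant = do.call(rbind, c(quant, list(make.row.names = FALSE))),
    diffs = all_diffs,
    stats = do.call(rbind, c(stats_rows, list(make.row.names = FALSE))),
    calls = calls,
    donors = donors,
    params = list(peptide_log_e_max = peptide_log_e_max,
                  protein_log_e_max = protein_log_e_max,
                  min_unique_peptides = min_unique_peptides,
                  z_threshold = z_threshold, min_pairs = min_pairs,
                  robust_sd = robust_sd, mode_unique_rule = mode_unique_rule,
                  inclusive = inclusive)
  ), class = "lfqpair")
}

#' @export
print.lfqpair <- function(x, ...) {
  n_runs <- length(unique(paste(x$quant$donor_id, x$quant$condition)))
  cat("Paired label-free differential analysis\n")
  cat(sprintf("  %d donor pairs, %d runs, %d proteins quantified in >= 1 run\n",
              length(x$donors), n_runs, length(unique(x$quant$accession))))
  cat(sprintf("  consensus (|Z| >= %g in >= %d/%d donors): %d increased, %d decreased\n",
              x$params$z_threshold, x$params$min_pairs, length(x$donors),
              sum(x$calls$direction == "increased"),
              sum(x$calls$direction == "decreased")))
  invisible(x)
}

#' @export
summary.lfqpair <- function(object, ...) {
  st <- object$stats
  st$fold_at_2sd <- 2^(2 * st$central_sd)
  out <- list(stats = st, donors = object$donors,
              n_increased = sum(object$calls$direction == "increased"),
              n_decreased = sum(object$calls$direction == "decreased"),
              n_tested = nrow(object$calls), params = object$params)
  class(out) <- "summary.lfqpair"
  out
}

#' @export
print.summary.lfqpair <- function(x, ...) {
  cat("Per-donor central difference populations:\n")
  print(x$stats, row.names = FALSE, digits = 4)
  cat(sprintf("\n%d proteins tested: %d increased, %d decreased (|Z| >= %g in >= %d/%d donors)\n",
              x$n_tested, x$n_increased, x$n_decreased, x$params$z_threshold,
              x$params$min_pairs, length(x$donors)))
  cat("fold_at_2sd is the intensity fold change equivalent to a 2 SD shift.\n")
  invisible(x)
}

#' Per-donor Z-score matrix of a fitted analysis
#'
#' @param object An \code{lfqpair} fit.
#' @param ... Unused.
#' @return A numeric matrix (proteins x donors) of normalised differences;
#'   \code{NA} where a protein was not quantifiable in a donor pair.
#' @export
coef.lfqpair <- function(object, ...) {
  acc <- sort(unique(object$diffs$accession))
  z <- matrix(NA_real_, length(acc), length(object$donors),
              dimnames = list(acc, object$donors))
  z[cbind(match(object$diffs$accession, acc),
          match(object$diffs$donor_id, object$donors))] <- object$diffs$Z
  z
}

#' Difference-distribution histograms of a fitted analysis
#'
#' One panel per donor: the distribution of paired log2 differences D with
#' the central (both-mode) population in grey, mode-unique observations in
#' colour, and the qualification boundaries at \code{±z_threshold} central
#' SDs.
#'
#' @param x An \code{lfqpair} fit.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.lfqpair <- function(x, ...) {
  donors <- x$donors
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(donors)))
  on.exit(graphics::par(old))
  for (d in donors) {
    dd <- x$diffs[x$diffs$donor_id == d, ]
    st <- x$stats[x$stats$donor_id == d, ]
    graphics::hist(dd$D[dd$mode == "both"], breaks = 50, col = "grey80",
                   border = NA, main = paste("Donor", d),
                   xlab = "D = log2(IFN) - log2(CTL)",
                   xlim = range(dd$D), ...)
    graphics::rug(dd$D[dd$mode == "ifn_only"], col = "firebrick")
    graphics::rug(dd$D[dd$mode == "ctl_only"], col = "steelblue", side = 3)
    graphics::abline(v = st$central_mean +
                       c(-1, 1) * x$params$z_threshold * st$central_sd,
                     lty = 2)
  }
  invisible(x)
}

#' Assemble and validate a pipeline configuration
#'
#' @param psm_paths Named character vector or list of PSM TSV paths, names
#'   \code{"<donor>_<condition>"}; or a directory containing files named
#'   \code{psm_<donor>_<condition>.tsv}.
#' @param out_dir Output directory for result tables and the report.
#' @param annotation_path Optional TM/SP annotation TSV.
#' @param transcript_path Optional transcript-response TSV.
#' @param donors Optional donor order.
#' @param ... Threshold and option overrides passed to [lfqpair()].
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(psm_paths, out_dir, annotation_path = NULL,
                            transcript_path = NULL, donors = NULL, ...) {
  if (length(psm_paths) == 1L && is.character(psm_paths) &&
      dir.exists(psm_paths)) {
    files <- list.files(psm_paths, pattern = "^psm_.*\\.tsv$",
                        full.names = TRUE)
    if (length(files) == 0L) {
      stop("no psm_<donor>_<condition>.tsv files found in ", psm_paths)
    }
    nm <- sub("^psm_", "", tools::file_path_sans_ext(basename(files)))
    psm_paths <- stats::setNames(as.list(files), nm)
  }
  psm_paths <- as.list(psm_paths)
  if (length(psm_paths) == 0L) stop("no PSM tables configured")
  if (is.null(names(psm_paths)) || any(!nzchar(names(psm_paths)))) {
    stop("psm_paths must be named '<donor>_<condition>'")
  }
  for (p in psm_paths) if (!file.exists(p)) stop("missing PSM table: ", p)
  if (!is.null(annotation_path) && !file.exists(annotation_path)) {
    stop("missing annotation table: ", annotation_path)
  }
  if (!is.null(transcript_path) && !file.exists(transcript_path)) {
    stop("missing transcript table: ", transcript_path)
  }
  opts <- list(...)
  structure(list(psm_paths = psm_paths, out_dir = out_dir,
                 annotation_path = annotation_path,
                 transcript_path = transcript_path, donors = donors,
                 options = opts),
            class = "pipeline_config")
}

report_line <- function(con, ...) {
  writeLines(paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...), con)
}

#' Run the full pipeline from files to files
#'
#' Reads the configured PSM tables, fits the paired differential analysis,
#' applies the optional annotation steps, and writes every intermediate
#' table (per-run quantifications, per-donor differences, population
#' statistics, the consensus table, annotated calls) plus a timestamped
#' plain-text report embedding the resolved configuration. A stage failure
#' aborts with the stage name in the error.
#'
#' @param config A [pipeline_config()] object.
#' @return The fitted \code{lfqpair} object, invisibly, with the annotated
#'   consensus table attached as \code{annotated} when annotation tables
#'   were configured.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  runs <- stage("read", lapply(config$psm_paths, read_psm_table))
  fit <- stage("fit", do.call(lfqpair, c(list(runs = runs,
                                              donors = config$donors),
                                         config$options)))
  annotated <- fit$calls
  if (!is.null(config$annotation_path)) {
    annotated <- stage("annotate", classify_membrane_secreted(
      annotated, read_annotation_table(config$annotation_path)))
  }
  if (!is.null(config$transcript_path)) {
    annotated <- stage("crossref", crossref_transcript_response(
      annotated, read_transcript_table(config$transcript_path)))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  stage("write", {
    write_tsv(fit$quant, out("quantifications.tsv"))
    write_tsv(fit$diffs, out("differences.tsv"))
    write_tsv(fit$stats, out("population_stats.tsv"))
    write_tsv(fit$calls, out("consensus.tsv"))
    if (!identical(annotated, fit$calls)) {
      write_tsv(annotated, out("annotated_calls.tsv"))
    }
  })
  con <- file(out("report.txt"), "w", encoding = "UTF-8")
  on.exit(close(con))
  report_line(con, "paired label-free differential analysis report")
  report_line(con, "runs: ", length(runs), " (",
              paste(names(config$psm_paths), collapse = ", "), ")")
  per_run <- table(paste(fit$quant$donor_id, fit$quant$condition, sep = "_"))
  for (k in names(per_run)) {
    report_line(con, "proteins quantified in ", k, ": ", per_run[[k]])
  }
  shared <- sum(table(fit$quant$accession) == length(per_run))
  report_line(con, "proteins quantified in every run: ", shared)
  report_line(con, "proteins tested: ", nrow(fit$calls))
  report_line(con, "consensus increased: ",
              sum(fit$calls$direction == "increased"))
  report_line(con, "consensus decreased: ",
              sum(fit$calls$direction == "decreased"))
  if ("category" %in% names(annotated)) {
    called <- annotated[annotated$direction != "none", ]
    for (cat_name in c("membrane", "secreted", "other", "unannotated")) {
      report_line(con, "called proteins in category ", cat_name, ": ",
                  sum(called$category == cat_name))
    }
  }
  if ("transcript_responsive" %in% names(annotated)) {
    called <- annotated[annotated$direction != "none", ]
    report_line(con, "called proteins with responsive transcripts: ",
                sum(called$transcript_responsive))
  }
  report_line(con, "resolved configuration:")
  p <- fit$params
  for (k in names(p)) report_line(con, "  ", k, " = ", p[[k]])
  fit$annotated <- annotated
  invisible(fit)
}
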