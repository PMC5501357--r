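# Cross-donor consensus: a protein is called differentially expressed when
# it changes by at least |z_threshold| SD in the same direction in at least
# min_pairs of the donor pairs. Donors with opposite or non-significant
# changes do not veto a call.

#' Per-donor qualification of a difference
#'
#' Classifies normalised differences as \code{up} (\code{Z >= z_threshold}),
#' \code{down} (\code{Z <= -z_threshold}) or \code{none}. The threshold is
#' inclusive by default. Mode-unique observations (detected in only one
#' condition) qualify either under the same common-scale Z rule
#' (\code{mode_unique_rule = "zscore"}, the default) or unconditionally in
#' the direction of their observed mode (\code{"always"}).
#'
#' @param diff A difference data frame (or one row of it) with \code{Z} and
#'   \code{mode} filled.
#' @param z_threshold Qualification threshold in central-population SD units
#'   (default 2).
#' @param inclusive Treat the threshold as inclusive (default \code{TRUE}).
#' @param mode_unique_rule \code{"zscore"} or \code{"always"}.
#' @return A character vector (one element per row) of \code{"up"},
#'   \code{"down"}, \code{"none"}.
#' @export
qualify_pair <- function(diff, z_threshold = 2, inclusive = TRUE,
                         mode_unique_rule = c("zscore", "always")) {
  mode_unique_rule <- match.arg(mode_unique_rule)
  z <- diff$Z
  if (anyNA(z)) stop("Z must be computed before qualification")
  if (inclusive) {
    out <- ifelse(z >= z_threshold, "up",
                  ifelse(z <= -z_threshold, "down", "none"))
  } else {
    out <- ifelse(z > z_threshold, "up",
                  ifelse(z < -z_threshold, "down", "none"))
  }
  if (mode_unique_rule == "always") {
    out[diff$mode == "ifn_only"] <- "up"
    out[diff$mode == "ctl_only"] <- "down"
  }
  out
}

#' Consensus call for a single protein across donors
#'
#' Counts how many donors qualify the protein up and how many down;
#' \code{direction} is \code{increased} (\code{decreased}) when at least
#' \code{min_pairs} donors qualify in that direction, else \code{none}.
#' Opposite-direction and non-significant donors are ignored, never vetoes.
#'
#' @param diffs Normalised difference rows for one accession (at most one
#'   per donor).
#' @param donors Character vector fixing donor display order.
#' @param min_pairs Minimum consistent donors for a call (default 3).
#' @inheritParams qualify_pair
#' @return A one-row data frame: \code{accession}, \code{direction},
#'   \code{n_qualifying}, \code{n_up}, \code{n_down}, and one display column
#'   per donor (named \code{display_<donor>}).
#' @export
consensus_call <- function(diffs, donors, min_pairs = 3L, z_threshold = 2,
                           inclusive = TRUE,
                           mode_unique_rule = c("zscore", "always")) {
  mode_unique_rule <- match.arg(mode_unique_rule)
  if (nrow(diffs) == 0L) stop("no differences supplied")
  if (length(unique(diffs$accession)) != 1L) {
    stop("consensus_call expects rows for a single accession")
  }
  if (anyDuplicated(diffs$donor_id)) {
    stop("two differences for one donor (accession ", diffs$accession[1L], ")")
  }
  if (!all(diffs$donor_id %in% donors)) {
    stop("difference rows reference donors outside the configured order")
  }
  qual <- qualify_pair(diffs, z_threshold, inclusive, mode_unique_rule)
  n_up <- sum(qual == "up")
  n_down <- sum(qual == "down")
  if (n_up >= min_pairs && n_down >= min_pairs) {
    stop("conflicting consensus for ", diffs$accession[1L],
         ": both directions reach min_pairs")
  }
  direction <- if (n_up >= min_pairs) "increased"
  else if (n_down >= min_pairs) "decreased" else "none"
  n_qual <- switch(direction, increased = n_up, decreased = n_down, 0L)
  idx <- match(donors, diffs$donor_id)
  disp <- fold_display(diffs$D[idx], diffs$mode[idx],
                       direction = if (direction == "decreased") "decreased"
                       else "increased")
  out <- data.frame(accession = diffs$accession[1L], direction = direction,
                    n_qualifying = as.integer(n_qual),
                    n_up = as.integer(n_up), n_down = as.integer(n_down),
                    stringsAsFactors = FALSE)
  disp_df <- as.data.frame(as.list(disp), stringsAsFactors = FALSE)
  names(disp_df) <- paste0("display_", donors)
  cbind(out, disp_df)
}

#' Consensus table over all proteins
#'
#' Applies [consensus_call()] to every accession present in the pooled
#' per-donor differences.
#'
#' @param diffs Normalised differences for all donors (row-bound).
#' @inheritParams consensus_call
#' @return A data frame, one row per accession (accession-sorted), with the
#'   columns of [consensus_call()].
#' @export
consensus_table <- function(diffs, donors, min_pairs = 3L, z_threshold = 2,
                            inclusive = TRUE,
                            mode_unique_rule = c("zscore", "always")) {
  mode_unique_rule <- match.arg(mode_unique_rule)
  pieces <- lapply(split(diffs, diffs$accession), consensus_call,
                   donors = donors, min_pairs = min_pairs,
                   z_threshold = z_threshold, inclusive = inclusive,
                   mode_unique_rule = mode_unique_rule)
  out <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- consensus_call(
      data.frame(accession = "x", donor_id = donors[1L], mode = "both",
                 D = 0, Z = 0, stringsAsFactors = FALSE),
      donors = donors)[0L, ]
  }
  out[order(out$accession), , drop = FALSE]
}

#' Per-donor display token
#'
#' Reproduces the reporting convention of the published tables: both-mode
#' proteins show the fold change \code{2^D} (or \code{2^-D} in
#' decreased-direction tables, "fold decrease") rounded to one decimal;
#' proteins detected only after treatment show \code{"IFN"}, only in the
#' untreated sample \code{"CTL"}, and proteins not detected in the donor
#' show an en dash.
#'
#' @param D Numeric vector of log2 differences (\code{NA} = absent).
#' @param mode Character vector of modes (\code{NA} = absent).
#' @param direction \code{"increased"} or \code{"decreased"} (selects fold
#'   increase vs fold decrease for both-mode entries).
#' @return Character vector of display tokens.
#' @export
fold_display <- function(D, mode, direction = c("increased", "decreased")) {
  direction <- match.arg(direction)
  fold <- if (direction == "decreased") 2^(-D) else 2^D
  out <- ifelse(is.na(mode), "\u2013",
                ifelse(mode == "ifn_only", "IFN",
                       ifelse(mode == "ctl_only", "CTL",
                              formatC(round(fold, 1L), format = "f",
                                      digits = 1L))))
  out
}
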