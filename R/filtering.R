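#' Filtering thresholds for high-confidence interaction selection
#'
#' Holds the four thresholds of the dual high-confidence selection:
#' the combined-score cut applied to functional/predicted evidence and the
#' physical-interaction rule set (publication support, cross-species
#' conservation, MI score).
#'
#' The combined-score cut is *strict* (`> combined_threshold`); the MI cut is
#' *inclusive* (`>= mi_threshold`).  Defaults follow the study conventions:
#' 0.700 combined, 0.431 MI, at least 3 publications, conserved in at least
#' one species.
#'
#' @param combined_threshold combined score above which a functional record
#'   is kept (strict).
#' @param mi_threshold minimum MI score for a physical record (inclusive).
#' @param min_publications minimum number of supporting publications.
#' @param min_conserved_species minimum number of species the interaction is
#'   conserved in.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(combined_threshold = 0.700,
                          mi_threshold = 0.431,
                          min_publications = 3L,
                          min_conserved_species = 1L) {
  stopifnot(
    is.numeric(combined_threshold), combined_threshold >= 0, combined_threshold <= 1,
    is.numeric(mi_threshold), mi_threshold >= 0, mi_threshold <= 1,
    is.numeric(min_publications), min_publications >= 0,
    is.numeric(min_conserved_species), min_conserved_species >= 0
  )
  structure(
    list(combined_threshold = combined_threshold,
         mi_threshold = mi_threshold,
         min_publications = as.integer(min_publications),
         min_conserved_species = as.integer(min_conserved_species)),
    class = "filter_config"
  )
}

#' @export
print.filter_config <- function(x, ...) {
  cat("High-confidence filter configuration\n")
  cat(sprintf("  combined score   > %.3f (strict)\n", x$combined_threshold))
  cat(sprintf("  MI score        >= %.3f (inclusive)\n", x$mi_threshold))
  cat(sprintf("  publications    >= %d\n", x$min_publications))
  cat(sprintf("  conserved in    >= %d species\n", x$min_conserved_species))
  invisible(x)
}

#' Noisy-OR combination of evidence-channel probabilities
#'
#' Combines independent per-channel confidence scores into a single
#' probability: `S = 1 - prod(1 - S_i)`.  An empty score list yields 0;
#' `NA` entries (absent channels) are ignored.
#'
#' @param channel_scores numeric vector of probabilities in `[0, 1]`.
#' @return The combined probability.
#' @export
combine_scores <- function(channel_scores) {
  s <- channel_scores[!is.na(channel_scores)]
  if (length(s) == 0) return(0)
  if (any(s < 0 | s > 1)) {
    stop("channel score(s) outside [0,1]", call. = FALSE)
  }
  1 - prod(1 - s)
}

# row-wise combined score across all score_* columns of an evidence table
.combined_scores <- function(ev) {
  sc <- channel_columns(ev)
  if (length(sc) == 0) return(rep(0, NROW(ev)))
  m <- as.matrix(ev[, sc, drop = FALSE])
  if (any(!is.na(m) & (m < 0 | m > 1))) {
    stop("channel score(s) outside [0,1]", call. = FALSE)
  }
  m[is.na(m)] <- 0
  1 - apply(1 - m, 1, prod)
}

#' Select high-confidence functional interactions by combined score
#'
#' Recomputes the combined score of every record from its channel scores via
#' [combine_scores()] (never trusting a precomputed column) and keeps the
#' records whose combined score strictly exceeds `cfg$combined_threshold`.
#'
#' @param ev canonicalized evidence data frame.
#' @param cfg a [filter_config()].
#' @return The kept records, with a populated `combined_score` column.
#' @export
filter_functional <- function(ev, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  ev$combined_score <- .combined_scores(ev)
  out <- ev[ev$combined_score > cfg$combined_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select high-confidence physical interactions
#'
#' Keeps records that are physical, supported by at least
#' `cfg$min_publications` publications, conserved in at least
#' `cfg$min_conserved_species` species, and have an MI score of at least
#' `cfg$mi_threshold` (inclusive).  Records with a missing MI score are
#' dropped.
#'
#' @inheritParams filter_functional
#' @return The kept records.
#' @export
filter_physical <- function(ev, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  keep <- !is.na(ev$is_physical) & ev$is_physical &
    ev$n_publications >= cfg$min_publications &
    ev$n_conserved_species >= cfg$min_conserved_species &
    !is.na(ev$mi_score) & ev$mi_score >= cfg$mi_threshold
  out <- ev[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
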