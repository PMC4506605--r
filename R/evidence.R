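#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef lm median quantile rbeta rbinom residuals rpois runif setNames
#' @importFrom utils read.delim write.table head
NULL

# Column layout shared by every evidence table in the package.  Channel
# scores occupy an arbitrary number of columns prefixed "score_".
.evidence_fixed_cols <- c(
  "protein_a", "protein_b", "mi_score", "n_publications",
  "is_physical", "n_conserved_species"
)

#' Names of the evidence-channel score columns of an evidence table
#'
#' @param ev evidence data frame.
#' @return Character vector of column names starting with `"score_"`.
#' @export
channel_columns <- function(ev) {
  grep("^score_", names(ev), value = TRUE)
}

.parse_logical <- function(x, column) {
  x0 <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x0))
  out[x0 %in% c("1", "true", "yes")] <- TRUE
  out[x0 %in% c("0", "false", "no")] <- FALSE
  bad <- which(is.na(out) & !(x0 %in% c("", "na")))
  if (length(bad)) {
    stop(sprintf("column '%s': unparseable logical value '%s' (row %d)",
                 column, x0[bad[1]], bad[1]), call. = FALSE)
  }
  out
}

#' Read a protein annotation table
#'
#' Parses a tab-separated annotation table with columns `accession`,
#' `gene_symbol`, `signal_peptide`, `transmembrane` and `compartments`
#' (semicolon-separated subset of `sperm`/`egg`).  Boolean columns accept
#' 0/1, true/false and yes/no case-insensitively.
#'
#' @param path path to a TSV file with a header row.
#' @return A data frame with columns `accession`, `gene_symbol`,
#'   `has_signal_peptide`, `has_transmembrane` (logical) and `compartments`
#'   (semicolon-separated character).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  raw <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("accession", "gene_symbol", "signal_peptide",
                "transmembrane", "compartments")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("annotation table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ann <- data.frame(
    accession = trimws(raw$accession),
    gene_symbol = trimws(raw$gene_symbol),
    has_signal_peptide = .parse_logical(raw$signal_peptide, "signal_peptide"),
    has_transmembrane = .parse_logical(raw$transmembrane, "transmembrane"),
    compartments = trimws(raw$compartments),
    stringsAsFactors = FALSE
  )
  if (any(ann$accession == "")) {
    stop("annotation table contains an empty accession", call. = FALSE)
  }
  dup <- unique(ann$accession[duplicated(ann$accession)])
  if (length(dup)) {
    stop("duplicate accession(s) in annotation table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  ann
}

.membrane_flag <- function(ann) {
  ann$has_signal_peptide | ann$has_transmembrane
}

#' Validate, canonicalize and merge interaction evidence
#'
#' Canonicalizes each pair so that `protein_a` sorts before `protein_b`,
#' rejects self-interactions and out-of-range scores, and merges duplicate
#' pairs by taking per channel the maximum score, the maximum publication and
#' conservation counts, and the logical OR of the physical flag.  The merge is
#' idempotent and independent of row order.
#'
#' @param ev data frame with columns `protein_a`, `protein_b`, zero or more
#'   `score_*` channel columns, `mi_score`, `n_publications`, `is_physical`,
#'   `n_conserved_species`.
#' @return The canonicalized, merged evidence data frame, ordered by pair.
#' @export
as_evidence <- function(ev) {
  missing <- setdiff(.evidence_fixed_cols, names(ev))
  if (length(missing)) {
    stop("evidence table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ev$protein_a <- as.character(ev$protein_a)
  ev$protein_b <- as.character(ev$protein_b)
  selfs <- which(ev$protein_a == ev$protein_b)
  if (length(selfs)) {
    stop("self-interaction(s) at row(s): ",
         paste(head(selfs, 10), collapse = ", "), call. = FALSE)
  }
  sc <- channel_columns(ev)
  for (col in c(sc, "mi_score")) {
    v <- as.numeric(ev[[col]])
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad)) {
      stop(sprintf("column '%s': score outside [0,1] at row(s): %s",
                   col, paste(head(bad, 10), collapse = ", ")), call. = FALSE)
    }
    ev[[col]] <- v
  }
  ev$n_publications <- as.integer(ev$n_publications)
  ev$n_conserved_species <- as.integer(ev$n_conserved_species)
  if (!is.logical(ev$is_physical)) {
    ev$is_physical <- .parse_logical(ev$is_physical, "is_physical")
  }
  bad <- which(is.na(ev$n_publications) | ev$n_publications < 0 |
               is.na(ev$n_conserved_species) | ev$n_conserved_species < 0)
  if (length(bad)) {
    stop("negative or missing count at row(s): ",
         paste(head(bad, 10), collapse = ", "), call. = FALSE)
  }
  # canonical order within pair
  swap <- ev$protein_a > ev$protein_b
  if (any(swap)) {
    tmp <- ev$protein_a[swap]
    ev$protein_a[swap] <- ev$protein_b[swap]
    ev$protein_b[swap] <- tmp
  }
  key <- paste(ev$protein_a, ev$protein_b, sep = "\r")
  if (anyDuplicated(key)) {
    idx <- split(seq_len(nrow(ev)), key)
    max_na <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
    rows <- lapply(idx, function(i) {
      r <- ev[i[1], , drop = FALSE]
      for (col in c(sc, "mi_score")) r[[col]] <- max_na(ev[[col]][i])
      r$n_publications <- max(ev$n_publications[i])
      r$n_conserved_species <- max(ev$n_conserved_species[i])
      r$is_physical <- any(ev$is_physical[i], na.rm = TRUE)
      r
    })
    ev <- do.call(rbind, rows)
  }
  ev <- ev[order(ev$protein_a, ev$protein_b), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Read an interaction-evidence table
#'
#' Reads a TSV of candidate interactions and returns the canonicalized,
#' merged evidence table (see [as_evidence()]).  Unset numeric cells may be
#' empty or `NA`.
#'
#' @inherit as_evidence return
#' @param path path to a TSV file.
#' @export
read_evidence <- function(path) {
  if (!file.exists(path)) stop("evidence file not found: ", path, call. = FALSE)
  raw <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  as_evidence(raw)
}

#' Write an evidence table to TSV
#'
#' @param ev canonicalized evidence data frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_evidence <- function(ev, path) {
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
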