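#' ArgC-like in-silico digestion
#'
#' Emulates trypsin digestion of lysine-derivatized histones: chemical
#' blocking of lysines restricts cleavage to the C-terminal side of arginine
#' ("ArgC-like" specificity). Emits every peptide window carrying 0 to
#' \code{max_missed} internal missed cleavages and at least \code{min_length}
#' residues, with 1-based inclusive protein coordinates.
#'
#' @param sequence Protein sequence (uppercase one-letter amino acids).
#' @param max_missed Maximum internal missed cleavage sites (default 2).
#' @param min_length Minimum peptide length in residues (default 4).
#' @param proline_rule If \code{TRUE} (default), cleavage is suppressed when
#'   the arginine is followed by proline; this reproduces the canonical
#'   histone windows (e.g. H3 41-49 YRPGTVALR spans an internal R-P).
#' @return data.frame with columns \code{start}, \code{end} (1-based
#'   inclusive), \code{sequence}, \code{missed}; one row per window, ordered
#'   by start then end.
#' @examples
#' h3n <- "ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHRYRPGTVALR"
#' digest_argc(h3n, max_missed = 0)$sequence
#' @export
digest_argc <- function(sequence, max_missed = 2, min_length = 4,
                        proline_rule = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0)
    stop("sequence must be a single nonempty string")
  if (max_missed < 0) stop("max_missed must be >= 0")
  chars <- strsplit(sequence, "")[[1]]
  aa <- names(aa_compositions())
  bad <- which(!(chars %in% aa))
  if (length(bad) > 0)
    stop("non-amino-acid character '", chars[bad[1]], "' at position ", bad[1])
  n <- length(chars)
  # cut points: cleavage AFTER position i when residue i is R (suppressed
  # before P), plus the protein C-terminus
  cuts <- which(chars == "R")
  if (proline_rule)
    cuts <- cuts[!(cuts < n & chars[pmin(cuts + 1, n)] == "P")]
  cuts <- cuts[cuts < n]
  bounds <- c(0L, cuts, n)  # peptide i spans bounds[i]+1 .. bounds[i+1]
  k <- length(bounds) - 1L
  out <- vector("list", 0)
  for (i in seq_len(k)) {
    for (j in i:min(k, i + max_missed)) {
      s <- bounds[i] + 1L
      e <- bounds[j + 1L]
      if (e - s + 1L >= min_length) {
        out[[length(out) + 1L]] <-
          data.frame(start = s, end = e,
                     sequence = substr(sequence, s, e),
                     missed = j - i, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      sequence = character(0), missed = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Make a peptide window
#'
#' A peptide window is a digested stretch of a parent protein, identified by
#' protein id and 1-based inclusive coordinates (the field's "H3 9-17"
#' naming).
#'
#' @param protein Parent protein id (e.g. \code{"H3"}).
#' @param start,end 1-based inclusive coordinates in the protein.
#' @param sequence The window's amino-acid sequence.
#' @param missed Missed-cleavage count (informational).
#' @return Object of class \code{peptide_window}.
#' @export
peptide_window <- function(protein, start, end, sequence, missed = 0L) {
  if (nchar(sequence) != end - start + 1)
    stop("sequence length does not match coordinates ", start, "-", end)
  structure(list(protein = protein, start = start, end = end,
                 sequence = sequence, missed = missed),
            class = "peptide_window")
}

#' Windows of a protein as peptide_window objects
#'
#' Convenience wrapper around [digest_argc()] that attaches the protein id.
#'
#' @inheritParams digest_argc
#' @param protein Protein id used to label the windows.
#' @return List of [peptide_window()] objects.
#' @export
digest_protein <- function(protein, sequence, max_missed = 2, min_length = 4,
                           proline_rule = TRUE) {
  d <- digest_argc(sequence, max_missed, min_length, proline_rule)
  lapply(seq_len(nrow(d)), function(i)
    peptide_window(protein, d$start[i], d$end[i], d$sequence[i], d$missed[i]))
}

window_id <- function(window) {
  paste0(window$protein, " ", window$start, "-", window$end)
}
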