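# Expected columns of a PSM table (one table per single-acylation search).
psm_columns <- function() {
  c("RawFile", "Scan", "Sequence", "Modifications", "Score",
    "LocalizationProb", "Decoy", "Contaminant", "SearchId", "Channel")
}

check_psm_table <- function(df, need = c("RawFile", "Scan", "Score")) {
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("PSM table missing column(s): ", paste(missing, collapse = ", "))
  invisible(df)
}

# number of positioned modifications in a modification string
n_mods <- function(modstring) {
  vapply(modstring, function(s) length(parse_mods_string(s)), integer(1),
         USE.NAMES = FALSE)
}

#' Merge parallel single-acylation search results
#'
#' Searching one acylation at a time keeps the search space (and false
#' discovery rate) manageable, but the parallel searches can assign the same
#' spectrum to different modified sequences. This merge resolves that
#' ambiguity by retaining, per spectrum, the peptide-to-spectrum match with
#' the highest search score. Identical assignments found by several searches
#' are deduplicated to a single row. Ties at equal score are broken
#' deterministically: fewer modified residues wins, then the
#' lexicographically smaller modification string, then search id.
#'
#' @param runs A list of PSM data.frames (one per search) or a single
#'   data.frame carrying a \code{SearchId} column. Required columns:
#'   \code{RawFile}, \code{Scan}, \code{Sequence}, \code{Modifications},
#'   \code{Score}; see \code{histoneacyl:::psm_columns()} for the full
#'   dialect.
#' @return Merged data.frame, one row per (RawFile, Scan), with a
#'   \code{Provenance} column recording the winning search and any discarded
#'   competitor assignments as \code{"search:sequence/mods(score)"}.
#' @examples
#' r1 <- data.frame(RawFile = "f", Scan = 1, Sequence = "PEPKR",
#'                  Modifications = "K4pr", Score = 80, SearchId = "pr")
#' r2 <- data.frame(RawFile = "f", Scan = 1, Sequence = "PEPKR",
#'                  Modifications = "K4bu", Score = 95, SearchId = "bu")
#' merge_searches(list(r1, r2))$Modifications  # "K4bu"
#' @export
merge_searches <- function(runs) {
  if (is.data.frame(runs)) runs <- list(runs)
  if (length(runs) == 0) stop("runs must be a nonempty list of PSM tables")
  runs <- lapply(runs, function(r) {
    check_psm_table(r, c("RawFile", "Scan", "Sequence", "Modifications", "Score"))
    if (is.null(r$SearchId)) r$SearchId <- NA_character_
    if (is.null(r$LocalizationProb)) r$LocalizationProb <- NA_real_
    if (is.null(r$Decoy)) r$Decoy <- FALSE
    if (is.null(r$Contaminant)) r$Contaminant <- FALSE
    if (is.null(r$Channel)) r$Channel <- "light"
    # within one run a spectrum must have a single interpretation
    key <- paste(r$RawFile, r$Scan)
    assign <- paste(r$Sequence, r$Modifications, r$Channel)
    for (k in unique(key[duplicated(key)])) {
      if (length(unique(assign[key == k])) > 1)
        stop("malformed run: spectrum (", k,
             ") has conflicting assignments within one search")
    }
    r[!duplicated(key), psm_columns(), drop = FALSE]
  })
  all <- do.call(rbind, runs)
  key <- paste(all$RawFile, all$Scan, sep = "\r")
  keep <- integer(0)
  prov <- character(0)
  for (k in unique(key)) {
    idx <- which(key == k)
    sub <- all[idx, , drop = FALSE]
    # deterministic preference: score desc, fewer mods, mod string, search id
    o <- order(-sub$Score, n_mods(sub$Modifications),
               sub$Modifications, sub$SearchId)
    win <- idx[o[1]]
    losers <- idx[o[-1]]
    losers <- losers[paste(all$Sequence[losers], all$Modifications[losers]) !=
                       paste(all$Sequence[win], all$Modifications[win])]
    keep <- c(keep, win)
    prov <- c(prov, if (length(losers) == 0) all$SearchId[win] else
      paste0(all$SearchId[win], "|discarded:",
             paste0(all$SearchId[losers], ":", all$Sequence[losers], "/",
                    all$Modifications[losers], "(", all$Score[losers], ")",
                    collapse = ";")))
  }
  out <- all[keep, , drop = FALSE]
  out$Provenance <- prov
  out <- out[order(out$RawFile, out$Scan), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Confidence-filter merged identifications
#'
#' Removes peptide-to-spectrum matches with search score below
#' \code{score_min} or modification-localization probability below
#' \code{loc_min} (both strict "less than": boundary values are retained),
#' plus any decoy or contaminant rows. The localization filter applies to
#' modified peptides only; an unmodified peptide has no site to localize and
#' passes vacuously.
#'
#' @param table Merged PSM data.frame ([merge_searches()]).
#' @param score_min Minimum retained score (default 40).
#' @param loc_min Minimum retained localization probability (default 0.75).
#' @return Filtered data.frame.
#' @export
filter_psms <- function(table, score_min = 40, loc_min = 0.75) {
  if (score_min < 0 || loc_min < 0) stop("thresholds must be >= 0")
  check_psm_table(table, c("Score", "LocalizationProb"))
  decoy <- if (!is.null(table$Decoy)) isTRUE_vec(table$Decoy) else FALSE
  contam <- if (!is.null(table$Contaminant)) isTRUE_vec(table$Contaminant) else FALSE
  modified <- if (!is.null(table$Modifications))
    n_mods(table$Modifications) > 0 else TRUE
  loc <- table$LocalizationProb
  loc_fail <- modified & !is.na(loc) & loc < loc_min
  loc_fail[modified & is.na(loc)] <- TRUE
  drop <- table$Score < score_min | loc_fail | decoy | contam
  out <- table[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) x & !is.na(x)
  else x %in% c("TRUE", "True", "true", "1", "+")
}

#' Collapse filtered PSMs to identified peptidoforms
#'
#' Groups retained PSMs by (sequence, positioned modifications) and reports,
#' per peptidoform: in how many samples (raw files) it was identified in the
#' light channel, whether it was also identified in the heavy super-SILAC
#' spike-in channel, and its modification category (pr, bu, other acyl, ac,
#' methyl, unmodified).
#'
#' @param table Filtered PSM data.frame.
#' @return data.frame keyed by \code{Sequence} and \code{Modifications} with
#'   columns \code{NSamples}, \code{SampleCounts} (named "sample:count"
#'   string), \code{SpikeIn} (heavy-channel identification), \code{SpikeInOnly}
#'   and \code{Category}.
#' @export
collapse_to_peptidoforms <- function(table) {
  check_psm_table(table, c("RawFile", "Sequence", "Modifications"))
  if (is.null(table$Channel)) table$Channel <- "light"
  key <- paste(table$Sequence, table$Modifications, sep = "\r")
  uk <- unique(key)
  rows <- lapply(uk, function(k) {
    sub <- table[key == k, , drop = FALSE]
    light <- sub[sub$Channel != "heavy", , drop = FALSE]
    counts <- table(light$RawFile)
    data.frame(
      Sequence = sub$Sequence[1],
      Modifications = sub$Modifications[1],
      NSamples = length(counts),
      SampleCounts = paste0(names(counts), ":", as.integer(counts), collapse = ","),
      SpikeIn = any(sub$Channel == "heavy"),
      SpikeInOnly = all(sub$Channel == "heavy"),
      Category = mod_category(sub$Modifications[1]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$Sequence, out$Modifications), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Modification category of a peptidoform
#'
#' Buckets a positioned-modification string the way identification counts
#' are reported: \code{"pr"} if any propionyl, else \code{"bu"} if any
#' butyryl, else \code{"other_acyl"} (cr/fo/ma/su/gl/hib/la), else
#' \code{"ac"}, else \code{"methyl"} (me1/me2/me3), else
#' \code{"unmodified"}.
#'
#' @param modstring Modification string, e.g. \code{"K9me1K14ac"}.
#' @return Character scalar.
#' @export
mod_category <- function(modstring) {
  vapply(modstring, function(s) {
    m <- parse_mods_string(s)
    if (length(m) == 0) return("unmodified")
    if ("pr" %in% m) return("pr")
    if ("bu" %in% m) return("bu")
    if (any(m %in% c("cr", "fo", "ma", "su", "gl", "hib", "la"))) return("other_acyl")
    if ("ac" %in% m) return("ac")
    "methyl"
  }, character(1), USE.NAMES = FALSE)
}
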