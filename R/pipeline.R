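#' Run the full quantification pipeline
#'
#' Chains the analysis stages on in-memory tables: merge the parallel
#' single-acylation PSM tables (best score per spectrum), apply the
#' confidence filters (score >= 40, localization >= 0.75, no
#' decoys/contaminants), collapse to identified peptidoforms, apply the
#' quantifiability rule (identified in >= 2 replicates, present in the
#' super-SILAC spike-in, clearly resolved peak), compute \%RA and L/H
#' ratios from the XIC table, pivot to a peptidoform-by-sample matrix,
#' log2-normalize, and (optionally) run two-sample t comparisons.
#'
#' Row counts in and out of every filtering stage are recorded in the
#' \code{log} element, mirroring the identification/quantification attrition
#' such experiments report.
#'
#' @param psm_runs List of PSM data.frames (one per search) or a single
#'   stacked data.frame.
#' @param xic XIC area table (see [quantify_xic()] for the dialect).
#' @param design Sample design table with columns \code{Sample},
#'   \code{Condition}, \code{Replicate}, and optionally \code{Treated}.
#' @param config A [pipeline_config()] (thresholds and normalization
#'   reference).
#' @param group_a,group_b Optional sample groups for a t-test comparison.
#' @param paired Paired comparison (default \code{FALSE}).
#' @return List with \code{merged}, \code{filtered}, \code{ids},
#'   \code{quantifiable} (keys), \code{quant}, \code{matrix},
#'   \code{normalized}, \code{comparison} (or \code{NULL}), \code{log}.
#' @export
run_pipeline <- function(psm_runs, xic, design, config = pipeline_config(),
                         group_a = NULL, group_b = NULL, paired = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  merged <- merge_searches(psm_runs)
  log$merged <- nrow(merged)
  filtered <- filter_psms(merged, config$score_min, config$loc_min)
  log$filtered <- nrow(filtered)
  log$filter_removed <- nrow(merged) - nrow(filtered)
  ids <- collapse_to_peptidoforms(filtered)
  log$peptidoforms_identified <- nrow(ids)

  # peptidoform keys: join identifications to XIC rows on (sequence, mods)
  xkey <- paste(xic$Sequence, xic$Mods, sep = "\r")
  ikey <- paste(ids$Sequence, ids$Modifications, sep = "\r")
  resolved <- tapply(xic$ResolvedPeak, xkey, all)
  ids$Resolved <- as.logical(resolved[ikey])
  ids$Resolved[is.na(ids$Resolved)] <- FALSE
  ids$Quantifiable <- quantifiability_filter(
    ids$NSamples, ids$SpikeIn, ids$Resolved, config$min_replicates)
  keep_keys <- unique(xic$Peptidoform[xkey %in% ikey[ids$Quantifiable]])
  log$peptidoforms_quantifiable <- length(keep_keys)

  quant <- quantify_xic(xic)
  mat <- ratio_matrix(quant, keep = keep_keys)
  untreated <- NULL
  if (config$reference == "untreated") {
    if (is.null(design$Treated))
      stop("reference = 'untreated' requires a Treated column in the design")
    untreated <- design$Sample[!isTRUE_vec(design$Treated)]
  }
  normalized <- if (nrow(mat) > 0)
    normalize_log2(mat, config$reference, untreated) else mat

  comparison <- NULL
  if (!is.null(group_a) && !is.null(group_b) && nrow(mat) > 0) {
    comparison <- compare_groups(normalized, group_a, group_b,
                                 paired = paired, alpha = config$alpha)
    log$tested <- nrow(comparison)
    log$significant <- sum(comparison$Significant)
  }
  list(merged = merged, filtered = filtered, ids = ids,
       quantifiable = keep_keys, quant = quant, matrix = mat,
       normalized = normalized, comparison = comparison, log = log)
}

#' Score assignment recovery against simulator truth
#'
#' Fraction of true spectrum assignments that survive merging and filtering
#' with the correct interpretation, among the true assignments that pass the
#' confidence thresholds themselves (a true PSM below the score or
#' localization cutoff is counted out of the denominator: the filter is
#' doing its stated job there, not failing to recover).
#'
#' @param filtered Filtered merged PSM table.
#' @param truth Truth assignment table (\code{RawFile}, \code{Scan},
#'   \code{Sequence}, \code{Modifications}).
#' @param psm_runs The simulated runs (to look up each truth row's own score
#'   and localization).
#' @param score_min,loc_min The thresholds in force.
#' @return List: \code{recovered}, \code{eligible}, \code{rate}.
#' @export
assignment_recovery <- function(filtered, truth, psm_runs,
                                score_min = 40, loc_min = 0.75) {
  all_psm <- if (is.data.frame(psm_runs)) psm_runs else do.call(rbind, psm_runs)
  tkey <- paste(truth$RawFile, truth$Scan, sep = "\r")
  akey <- paste(all_psm$RawFile, all_psm$Scan, sep = "\r")
  aassign <- paste(all_psm$Sequence, all_psm$Modifications, sep = "\r")
  tassign <- paste(truth$Sequence, truth$Modifications, sep = "\r")
  # the true row's own score/localization
  own <- match(paste(tkey, tassign), paste(akey, aassign))
  own_score <- all_psm$Score[own]
  own_loc <- all_psm$LocalizationProb[own]
  passes <- own_score >= score_min &
    (is.na(own_loc) | own_loc >= loc_min)
  fkey <- paste(filtered$RawFile, filtered$Scan, sep = "\r")
  fassign <- paste(filtered$Sequence, filtered$Modifications, sep = "\r")
  kept <- fassign[match(tkey, fkey)]
  recovered <- !is.na(kept) & kept == tassign
  list(recovered = sum(recovered & passes), eligible = sum(passes),
       rate = sum(recovered & passes) / sum(passes))
}

#' Per-peptidoform recovery error of mean log2 L/H
#'
#' Compares the pipeline's per-peptidoform, per-condition mean normalized
#' ratios with the simulator's ground truth on the same normalization scale
#' (truth log2 L/H centered the same way), returning the per-cell errors.
#'
#' @param normalized Normalized log2 matrix from [run_pipeline()].
#' @param truth_ra Simulator truth table (\code{truth$ra}).
#' @param design Design table.
#' @return data.frame with \code{Peptidoform}, \code{Condition},
#'   \code{Estimate}, \code{Truth}, \code{Error}.
#' @export
recovery_errors <- function(normalized, truth_ra, design) {
  pfs <- rownames(normalized)
  conds <- unique(design$Condition)
  # center truth rows like the all-samples normalization (row mean over
  # conditions weighted by replicate counts)
  n_rep <- table(design$Condition)[conds]
  rows <- list()
  for (pf in pfs) {
    tr <- truth_ra[truth_ra$Peptidoform == pf, , drop = FALSE]
    if (nrow(tr) == 0 || all(is.na(tr$Log2LH))) next
    tvals <- tr$Log2LH[match(conds, tr$Condition)]
    tmean <- sum(tvals * as.numeric(n_rep)) / sum(as.numeric(n_rep))
    for (cond in conds) {
      smps <- design$Sample[design$Condition == cond]
      est <- mean(normalized[pf, intersect(smps, colnames(normalized))],
                  na.rm = TRUE)
      if (!is.finite(est)) next
      tv <- tvals[match(cond, conds)] - tmean
      rows[[length(rows) + 1L]] <- data.frame(
        Peptidoform = pf, Condition = cond, Estimate = est, Truth = tv,
        Error = est - tv, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(Peptidoform = character(0), Condition = character(0),
                      Estimate = numeric(0), Truth = numeric(0),
                      Error = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
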