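#' Read a FASTA file
#'
#' Standard multi-record FASTA reader. Record ids are the first whitespace
#' token of each header; sequences are uppercased.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0) stop("no records in FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(toupper(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read / write the package's TSV dialect
#'
#' Tab-separated, header line, no quoting; missing values are written as
#' empty fields and both empty fields and \code{"NA"} are read back as
#' missing. Round-trips losslessly for the table types the pipeline touches.
#'
#' @param df data.frame to write.
#' @param path File path.
#' @return \code{read_tsv}: data.frame. \code{write_tsv}: invisibly,
#'   \code{path}.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", na.strings = c("", "NA"),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Pipeline configuration
#'
#' Validates and normalizes the threshold set driving a pipeline run. All
#' stated cutoffs live here: the score and localization-probability filters,
#' the minimum replicate identifications, the significance level, the isobar
#' mass tolerance and the normalization reference. Unknown keys are
#' rejected.
#'
#' @param ... Configuration values, or a single named list. Recognized keys:
#'   \code{protocol}, \code{score_min} (default 40), \code{loc_min} (0.75),
#'   \code{min_replicates} (2), \code{alpha} (0.05), \code{tol_ppm} (10),
#'   \code{reference} ("all_samples"), \code{seed}.
#' @param path Optional YAML file to read the values from.
#' @return Object of class \code{pipeline_config} (a validated list).
#' @export
pipeline_config <- function(..., path = NULL) {
  vals <- if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else {
    dots <- list(...)
    if (length(dots) == 1 && is.list(dots[[1]]) && is.null(names(dots)))
      dots[[1]] else dots
  }
  defaults <- list(protocol = "D3Ac-PIC", score_min = 40, loc_min = 0.75,
                   min_replicates = 2, alpha = 0.05, tol_ppm = 10,
                   reference = "all_samples", seed = 1L)
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, vals)
  if (cfg$score_min < 0) stop("score_min must be >= 0")
  if (cfg$loc_min < 0 || cfg$loc_min > 1) stop("loc_min must lie in [0, 1]")
  if (cfg$min_replicates < 1) stop("min_replicates must be >= 1")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (cfg$tol_ppm <= 0) stop("tol_ppm must be > 0")
  cfg$protocol <- match.arg(cfg$protocol, protocol_names())
  cfg$reference <- match.arg(cfg$reference, c("all_samples", "untreated"))
  structure(cfg, class = "pipeline_config")
}
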