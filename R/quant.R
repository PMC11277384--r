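#' Percent relative abundance within a peptide group
#'
#' The \%RA of one modified form of a peptide is its extracted-ion
#' chromatogram area divided by the summed areas of all observed forms of
#' that peptide, times 100. Computed per channel per sample; the values of a
#' group sum to 100 by construction.
#'
#' @param areas Numeric vector of XIC areas (>= 0) for the observed forms of
#'   one peptide window in one sample/channel; \code{NA} entries (missing
#'   records) are excluded from the denominator and returned as \code{NA}.
#' @return Numeric vector of \%RA values in [0, 100]; all-\code{NA} (or
#'   all-zero) input yields all \code{NA} (group non-quantifiable, no
#'   division by zero).
#' @examples
#' relative_abundance(c(500, 300, 200))  # 50 30 20
#' @export
relative_abundance <- function(areas) {
  if (any(areas < 0, na.rm = TRUE)) stop("areas must be >= 0")
  tot <- sum(areas, na.rm = TRUE)
  if (!any(!is.na(areas)) || tot == 0) return(rep(NA_real_, length(areas)))
  100 * areas / tot
}

#' Combinatorial per-modification \%RA
#'
#' Reporting path for per-modification abundances: the area of a peptide
#' carrying several modifications simultaneously is summed into the area of
#' each single modification it carries (a me1+ac form counts toward both me1
#' and ac). To limit the influence of detection efficiency, group areas are
#' first rescaled to a fixed total of 1e9, then per-modification \%RA is the
#' summed area over 1e9, times 100. A value can exceed the unmodified form's
#' \%RA but never 100. Forms with an empty modification set feed the
#' \code{"unmod"} bucket only.
#'
#' @param areas Numeric vector of areas for the forms of one peptide group.
#' @param mod_sets List (same length) of character vectors naming the single
#'   modifications each form carries, e.g. \code{list(character(0), "me1",
#'   "ac", c("me1", "ac"))}. Site-resolved names like \code{"K9me1"} work
#'   equally; summing is by exact element.
#' @param total Target total area after rescaling (default 1e9).
#' @return Named numeric vector of per-modification \%RA values, including an
#'   \code{"unmod"} entry.
#' @examples
#' sum_combinatorial(c(400, 300, 200, 100),
#'                   list(character(0), "me1", "ac", c("me1", "ac")))
#' # unmod 40, me1 40, ac 30
#' @export
sum_combinatorial <- function(areas, mod_sets, total = 1e9) {
  stopifnot(length(areas) == length(mod_sets))
  keep <- !is.na(areas)
  areas <- areas[keep]; mod_sets <- mod_sets[keep]
  if (length(areas) == 0 || sum(areas) == 0)
    return(stats::setNames(numeric(0), character(0)))
  scaled <- areas * (total / sum(areas))
  mods <- unique(unlist(mod_sets))
  out <- c(unmod = sum(scaled[vapply(mod_sets, length, integer(1)) == 0]))
  for (m in mods)
    out[m] <- sum(scaled[vapply(mod_sets, function(s) m %in% s, logical(1))])
  100 * out / total
}

#' Light/heavy ratio from \%RA values
#'
#' Divides the light-channel \%RA by the heavy-channel (super-SILAC
#' spike-in) \%RA of the same peptidoform. Because the summed forms of a
#' peptide are constant across samples, the ratio of relative abundances
#' corrects for different amounts of starting material: rescaling every area
#' in a sample leaves every ratio unchanged.
#'
#' @param light_ra,heavy_ra \%RA values (vectors recycle as usual).
#' @return Ratio; \code{NA} (missing, not infinity) where the heavy \%RA is
#'   zero or missing.
#' @export
lh_ratio <- function(light_ra, heavy_ra) {
  out <- light_ra / heavy_ra
  out[is.na(heavy_ra) | (!is.na(heavy_ra) & heavy_ra == 0)] <- NA_real_
  out
}

#' Quantifiability rule
#'
#' A peptidoform is quantifiable only if (1) it was identified in at least
#' \code{min_replicates} replicates, (2) it was also identified in the
#' super-SILAC spike-in used as the internal standard, and (3) it
#' corresponds to a clearly resolved chromatographic peak (a
#' manual-validation surrogate carried as a boolean).
#'
#' @param n_replicates Integer vector: replicates with an identification.
#' @param spikein Logical vector: identified in the heavy spike-in channel.
#' @param resolved Logical vector: clearly resolved chromatographic peak.
#' @param min_replicates Minimum replicate identifications (default 2).
#' @return Logical vector.
#' @export
quantifiability_filter <- function(n_replicates, spikein, resolved,
                                   min_replicates = 2) {
  if (any(n_replicates < 0)) stop("replicate counts must be >= 0")
  n_replicates >= min_replicates & spikein & resolved
}

#' Build a quantification table from an XIC table
#'
#' Computes, per peptidoform and sample: light and heavy \%RA within the
#' peptide-window group, and the L/H ratio. Input mirrors the XIC dialect:
#' one row per (peptidoform, sample) with light and heavy areas. An absent
#' row is missing data; an area of 0 with a detected peak is a true zero.
#'
#' @param xic data.frame with columns \code{Peptidoform}, \code{Window},
#'   \code{Sample}, \code{LightArea}, \code{HeavyArea}, and optionally
#'   \code{ResolvedPeak}.
#' @return data.frame with added \code{LightRA}, \code{HeavyRA}, \code{LH}
#'   columns.
#' @export
quantify_xic <- function(xic) {
  need <- c("Peptidoform", "Window", "Sample", "LightArea", "HeavyArea")
  missing <- setdiff(need, names(xic))
  if (length(missing) > 0)
    stop("XIC table missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(paste(xic$Peptidoform, xic$Sample)))
    stop("more than one XIC record per (peptidoform, sample)")
  xic$LightRA <- NA_real_
  xic$HeavyRA <- NA_real_
  for (s in unique(xic$Sample)) {
    for (w in unique(xic$Window[xic$Sample == s])) {
      i <- which(xic$Sample == s & xic$Window == w)
      xic$LightRA[i] <- relative_abundance(xic$LightArea[i])
      xic$HeavyRA[i] <- relative_abundance(xic$HeavyArea[i])
    }
  }
  xic$LH <- lh_ratio(xic$LightRA, xic$HeavyRA)
  xic
}

#' Peptidoform-by-sample ratio matrix
#'
#' Pivots a quantification table ([quantify_xic()]) into a numeric matrix of
#' L/H ratios (rows: peptidoforms, columns: samples), optionally restricted
#' to quantifiable peptidoforms.
#'
#' @param quant Output of [quantify_xic()].
#' @param keep Optional character vector of peptidoform keys to retain.
#' @return Numeric matrix with dimnames; missing cells are \code{NA}.
#' @export
ratio_matrix <- function(quant, keep = NULL) {
  if (!is.null(keep)) quant <- quant[quant$Peptidoform %in% keep, , drop = FALSE]
  pfs <- sort(unique(quant$Peptidoform))
  samples <- sort(unique(quant$Sample))
  m <- matrix(NA_real_, length(pfs), length(samples),
              dimnames = list(pfs, samples))
  m[cbind(match(quant$Peptidoform, pfs), match(quant$Sample, samples))] <- quant$LH
  m
}

#' Log2-normalize a ratio matrix
#'
#' Takes log2 of the L/H ratios and centers each row on the mean log2 ratio
#' of the reference samples: either all samples (each row then has mean 0)
#' or the untreated samples only (changes are then expressed relative to the
#' untreated baseline).
#'
#' @param mat Peptidoform-by-sample matrix of L/H ratios (not yet logged).
#' @param reference \code{"all_samples"} or \code{"untreated"}.
#' @param untreated Character vector of untreated sample names (required for
#'   \code{reference = "untreated"}).
#' @return Matrix of normalized log2 ratios. Rows with no non-missing
#'   reference value are left all-\code{NA} with a warning.
#' @export
normalize_log2 <- function(mat, reference = c("all_samples", "untreated"),
                           untreated = NULL) {
  reference <- match.arg(reference)
  if (any(mat <= 0, na.rm = TRUE)) stop("ratios must be positive to take log2")
  lg <- log2(mat)
  ref_cols <- if (reference == "untreated") {
    if (is.null(untreated)) stop("untreated sample names required")
    if (!all(untreated %in% colnames(mat)))
      stop("unknown untreated sample(s): ",
           paste(setdiff(untreated, colnames(mat)), collapse = ", "))
    untreated
  } else colnames(mat)
  ref_mean <- rowMeans(lg[, ref_cols, drop = FALSE], na.rm = TRUE)
  empty <- !is.finite(ref_mean)
  if (any(empty)) {
    warning(sum(empty), " row(s) with no reference value left missing")
    ref_mean[empty] <- NA_real_
  }
  sweep(lg, 1, ref_mean, "-")
}

#' Mask Tukey-fence outliers
#'
#' Values above Q3 + 1.5*IQR or below Q1 - 1.5*IQR are considered outliers
#' and masked to \code{NA}. Quartiles use linear interpolation between order
#' statistics (R quantile type 7). With fewer than 4 non-missing values the
#' vector is returned unchanged (fences are meaningless).
#'
#' @param values Numeric vector (one peptidoform across the samples of a
#'   comparison, typically normalized log2 ratios).
#' @param k Fence multiplier (default 1.5).
#' @return \code{values} with outliers replaced by \code{NA}.
#' @examples
#' remove_outliers(c(1, 2, 3, 4, 100))  # 100 -> NA
#' @export
remove_outliers <- function(values, k = 1.5) {
  ok <- !is.na(values)
  if (sum(ok) < 4) return(values)
  q <- stats::quantile(values[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  out <- values > q[2] + k * iqr | values < q[1] - k * iqr
  values[ok & out] <- NA_real_
  values
}

#' Row-wise Tukey-fence masking of a matrix
#'
#' Applies [remove_outliers()] to each row, within each comparison group if
#' one is given.
#'
#' @param mat Numeric matrix (peptidoforms x samples).
#' @param groups Optional factor/character vector over columns; fences are
#'   then computed within each group separately.
#' @return Matrix with outliers masked.
#' @export
remove_outliers_matrix <- function(mat, groups = NULL) {
  if (is.null(groups)) {
    t(apply(mat, 1, remove_outliers))
  } else {
    stopifnot(length(groups) == ncol(mat))
    out <- mat
    for (g in unique(groups)) {
      cols <- which(groups == g)
      out[, cols] <- t(apply(mat[, cols, drop = FALSE], 1, remove_outliers))
    }
    out
  }
}

#' Mean-impute missing values
#'
#' For consumers that do not tolerate missing values (PCA, discriminant
#' analysis), each missing cell is replaced with the mean of that
#' peptidoform's non-missing values across conditions. Rows with no
#' observed value at all cannot be imputed and are dropped with a warning.
#'
#' @param mat Numeric matrix (peptidoforms x samples).
#' @return List with \code{matrix} (imputed, fully-missing rows dropped) and
#'   \code{imputed} (logical mask of imputed cells, same dim as the returned
#'   matrix).
#' @export
impute_missing <- function(mat) {
  all_missing <- rowSums(!is.na(mat)) == 0
  if (any(all_missing)) {
    warning("dropping ", sum(all_missing), " fully missing row(s): ",
            paste(utils::head(rownames(mat)[all_missing], 3), collapse = ", "))
    mat <- mat[!all_missing, , drop = FALSE]
  }
  mask <- is.na(mat)
  rm_ <- rowMeans(mat, na.rm = TRUE)
  for (i in seq_len(nrow(mat))) mat[i, mask[i, ]] <- rm_[i]
  list(matrix = mat, imputed = mask)
}
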