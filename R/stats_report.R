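#' Two-sample Student t test (pooled variance)
#'
#' Classical equal-variance two-sample t test on (typically) normalized log2
#' L/H ratios, with \code{df = nA + nB - 2} and a two-sided p value; or a
#' paired t test when \code{paired = TRUE} (matched samples, pairwise
#' complete). Degenerate inputs are handled explicitly: zero pooled variance
#' with equal means gives \code{t = 0, p = 1}; zero pooled variance with
#' unequal means is flagged degenerate with p reported at the machine lower
#' bound and a warning.
#'
#' @param a,b Numeric vectors (missing values dropped; for paired tests,
#'   pairwise-complete positions are used).
#' @param paired Paired test (default \code{FALSE}).
#' @param alpha Significance threshold on the raw p value (default 0.05).
#' @return List of class \code{comparison_result}: \code{estimate} (mean of
#'   a minus mean of b, or mean difference if paired), \code{t}, \code{df},
#'   \code{p}, \code{significant}, \code{degenerate}, \code{nA}, \code{nB}.
#' @examples
#' two_sample_t(c(1, 2, 3), c(4, 5, 6))$p  # ~0.0214
#' @export
two_sample_t <- function(a, b, paired = FALSE, alpha = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (paired) {
    if (length(a) != length(b)) stop("paired test requires equal-length groups")
    d <- a - b
    if (length(d) < 2) stop("insufficient replicates (need >= 2 pairs)")
    est <- mean(d)
    sd_d <- stats::sd(d)
    df <- length(d) - 1
    if (sd_d == 0) return(degenerate_result(est, df, length(d), length(d), alpha))
    tval <- est / (sd_d / sqrt(length(d)))
  } else {
    nA <- length(a); nB <- length(b)
    if (nA < 2 || nB < 2) stop("insufficient replicates (need >= 2 per group)")
    est <- mean(a) - mean(b)
    df <- nA + nB - 2
    sp2 <- ((nA - 1) * stats::var(a) + (nB - 1) * stats::var(b)) / df
    if (sp2 == 0) return(degenerate_result(est, df, nA, nB, alpha))
    tval <- est / sqrt(sp2 * (1 / nA + 1 / nB))
  }
  p <- 2 * stats::pt(-abs(tval), df)
  structure(list(estimate = est, t = tval, df = df, p = p,
                 significant = p < alpha, degenerate = FALSE,
                 nA = length(a), nB = length(b)),
            class = "comparison_result")
}

degenerate_result <- function(est, df, nA, nB, alpha) {
  if (est == 0) {
    structure(list(estimate = 0, t = 0, df = df, p = 1, significant = FALSE,
                   degenerate = FALSE, nA = nA, nB = nB),
              class = "comparison_result")
  } else {
    warning("zero pooled variance with unequal means; p reported at machine bound")
    structure(list(estimate = est, t = sign(est) * Inf, df = df,
                   p = .Machine$double.xmin, significant = TRUE,
                   degenerate = TRUE, nA = nA, nB = nB),
              class = "comparison_result")
  }
}

#' Row-wise group comparison of a quantification matrix
#'
#' Runs [two_sample_t()] for every peptidoform (row) between two sample
#' groups, optionally after Tukey-fence outlier masking computed per row
#' across the pooled samples of the comparison (pooled fences keep the
#' test calibrated; per-group fences on small groups shrink the variance
#' estimate and inflate the false-positive rate). Rows with fewer than two
#' usable values in either group are skipped. A
#' Benjamini-Hochberg adjusted p value is reported for reference; the
#' significance flag follows the raw p threshold.
#'
#' @param mat Normalized log2 ratio matrix (peptidoforms x samples).
#' @param group_a,group_b Character vectors of column (sample) names; must be
#'   disjoint.
#' @param paired Paired test; groups must then be ordered matched vectors.
#' @param alpha Raw p threshold (default 0.05).
#' @param mask_outliers Apply [remove_outliers()] per row across the
#'   comparison's samples first (default \code{TRUE}).
#' @return data.frame with one row per tested peptidoform: \code{Peptidoform},
#'   \code{Diff}, \code{t}, \code{df}, \code{p}, \code{p_adj},
#'   \code{Significant}.
#' @export
compare_groups <- function(mat, group_a, group_b, paired = FALSE,
                           alpha = 0.05, mask_outliers = TRUE) {
  if (length(intersect(group_a, group_b)) > 0) stop("groups must be disjoint")
  missing <- setdiff(c(group_a, group_b), colnames(mat))
  if (length(missing) > 0)
    stop("unknown sample(s): ", paste(missing, collapse = ", "))
  comb <- mat[, c(group_a, group_b), drop = FALSE]
  if (mask_outliers) {
    comb <- matrix(t(apply(comb, 1, remove_outliers)), nrow = nrow(comb),
                   dimnames = dimnames(comb))
  }
  A <- comb[, seq_along(group_a), drop = FALSE]
  B <- comb[, length(group_a) + seq_along(group_b), drop = FALSE]
  colnames(A) <- group_a; colnames(B) <- group_b
  rows <- lapply(rownames(mat), function(pf) {
    a <- A[pf, ]; b <- B[pf, ]
    if (paired) {
      ok <- !is.na(a) & !is.na(b)
      a <- a[ok]; b <- b[ok]
      if (length(a) < 2) return(NULL)
    } else if (sum(!is.na(a)) < 2 || sum(!is.na(b)) < 2) return(NULL)
    r <- two_sample_t(a, b, paired = paired, alpha = alpha)
    data.frame(Peptidoform = pf, Diff = r$estimate, t = r$t, df = r$df,
               p = r$p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(Peptidoform = character(0), Diff = numeric(0),
                      t = numeric(0), df = numeric(0), p = numeric(0),
                      p_adj = numeric(0), Significant = logical(0)))
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$Significant <- out$p < alpha
  rownames(out) <- NULL
  out
}

#' Volcano-plot input table
#'
#' One row per tested peptidoform with the mean log2 difference, -log10 p
#' and the significance flag, ordered by ascending p then key (deterministic).
#'
#' @param results Output of [compare_groups()].
#' @return data.frame with \code{Peptidoform}, \code{Diff}, \code{NegLog10P},
#'   \code{Significant}.
#' @export
volcano_table <- function(results) {
  if (nrow(results) == 0)
    return(data.frame(Peptidoform = character(0), Diff = numeric(0),
                      NegLog10P = numeric(0), Significant = logical(0)))
  out <- data.frame(Peptidoform = results$Peptidoform, Diff = results$Diff,
                    NegLog10P = -log10(results$p),
                    Significant = results$Significant,
                    stringsAsFactors = FALSE)
  out <- out[order(results$p, results$Peptidoform), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Imputed, z-scaled matrix for discriminant consumers
#'
#' Prepares the input expected by PCA / discriminant-analysis tools (whose
#' internals live outside this package): missing values are mean-imputed per
#' row, then each row is scaled to zero mean and unit variance (sample,
#' n-1, standard deviation). Constant rows have an undefined z-score and are
#' dropped with a warning.
#'
#' @param mat Normalized log2 ratio matrix.
#' @param classes Named character/factor vector mapping sample (column) name
#'   to class label; at least two distinct classes required.
#' @return List with \code{matrix} (z-scaled) and \code{classes} (aligned to
#'   the matrix columns).
#' @export
discriminant_input <- function(mat, classes) {
  if (is.null(names(classes))) {
    if (length(classes) != ncol(mat))
      stop("classes must be named by sample or match the column count")
    names(classes) <- colnames(mat)
  }
  missing <- setdiff(colnames(mat), names(classes))
  if (length(missing) > 0)
    stop("no class label for sample(s): ", paste(missing, collapse = ", "))
  cls <- classes[colnames(mat)]
  if (length(unique(cls)) < 2) stop("need at least two classes")
  imp <- impute_missing(mat)
  m <- imp$matrix
  sds <- apply(m, 1, stats::sd)
  constant <- sds == 0
  if (any(constant)) {
    warning("dropping ", sum(constant), " constant row(s)")
    m <- m[!constant, , drop = FALSE]
    sds <- sds[!constant]
  }
  z <- sweep(sweep(m, 1, rowMeans(m), "-"), 1, sds, "/")
  list(matrix = z, classes = cls)
}
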