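#' Classify isobaric ambiguity among peptidoforms
#'
#' Predicts which peptidoforms of one peptide window collapse into
#' indistinguishable species under a derivatization protocol. Two forms are
#' \code{indistinguishable} when their mass difference is within the mass
#' tolerance AND their total elemental compositions are identical after
#' mapping heavy isotopes to their light elements (deuterated and light
#' labels of the same acyl are chromatographically equivalent, so
#' isotope-blind composition equality predicts co-elution). Forms whose
#' isotope-blind compositions match but whose masses differ by more than the
#' tolerance are \code{mass_only_distinct} (they co-elute but the mass
#' spectrometer separates them - the deuterated-label design). Everything
#' else is \code{distinct}.
#'
#' Classes are the transitive closure of the indistinguishable relation, so
#' e.g. positional isomers of the same modification set all land in one
#' class.
#'
#' @param forms List of peptidoforms sharing one window and channel.
#' @param tol_ppm Mass tolerance in ppm of the peptidoform mass (default 10).
#' @param mods Modification table.
#' @return List with elements:
#'   \describe{
#'     \item{classes}{data.frame with one row per form: \code{form} (key),
#'       \code{mods}, \code{mass}, \code{class} (integer class id),
#'       \code{verdict}.}
#'     \item{pairs}{data.frame of all unordered pairs with \code{delta_mass}
#'       and pairwise \code{verdict}.}
#'   }
#' @export
ambiguity_classes <- function(forms, tol_ppm = 10, mods = mod_table()) {
  if (length(forms) == 0) stop("no forms supplied")
  wid <- vapply(forms, function(f) window_id(f$window), character(1))
  chan <- vapply(forms, function(f) f$channel, character(1))
  if (length(unique(wid)) > 1)
    stop("all forms must share one peptide window (got ",
         paste(unique(wid), collapse = ", "), ")")
  if (length(unique(chan)) > 1) stop("all forms must share one channel")
  n <- length(forms)
  comps <- lapply(forms, peptidoform_composition, mods = mods)
  masses <- vapply(comps, composition_mass, numeric(1))
  blind <- lapply(comps, isotope_blind)
  keys <- vapply(forms, peptidoform_key, character(1))

  pair_verdict <- function(i, j) {
    dm <- abs(masses[i] - masses[j])
    tol <- tol_ppm * 1e-6 * max(masses[i], masses[j])
    same_blind <- compositions_equal(blind[[i]], blind[[j]])
    if (same_blind && dm <= tol) "indistinguishable"
    else if (same_blind) "mass_only_distinct"
    else "distinct"
  }

  # union-find over the indistinguishable relation
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  pairs <- NULL
  if (n > 1) {
    idx <- utils::combn(n, 2)
    verdicts <- character(ncol(idx))
    for (k in seq_len(ncol(idx))) {
      i <- idx[1, k]; j <- idx[2, k]
      v <- pair_verdict(i, j)
      verdicts[k] <- v
      if (v == "indistinguishable") {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
    pairs <- data.frame(
      form_i = keys[idx[1, ]], form_j = keys[idx[2, ]],
      delta_mass = masses[idx[1, ]] - masses[idx[2, ]],
      verdict = verdicts, stringsAsFactors = FALSE
    )
  } else {
    pairs <- data.frame(form_i = character(0), form_j = character(0),
                        delta_mass = numeric(0), verdict = character(0))
  }
  roots <- vapply(seq_len(n), find, integer(1))
  class_id <- match(roots, unique(roots))
  # per-form verdict: member of a multi-form class -> indistinguishable;
  # singleton that co-elutes with some mass-separated partner ->
  # mass_only_distinct; otherwise distinct
  verdict <- character(n)
  for (i in seq_len(n)) {
    if (sum(class_id == class_id[i]) > 1) {
      verdict[i] <- "indistinguishable"
    } else if (n > 1 && any(vapply(seq_len(n)[-i], function(j)
                 pair_verdict(i, j) == "mass_only_distinct", logical(1)))) {
      verdict[i] <- "mass_only_distinct"
    } else {
      verdict[i] <- "distinct"
    }
  }
  classes <- data.frame(
    form = keys,
    mods = vapply(forms, function(f) mods_string(f$endogenous), character(1)),
    mass = masses, class = class_id, verdict = verdict,
    stringsAsFactors = FALSE
  )
  list(classes = classes, pairs = pairs)
}

#' Pairwise ambiguity verdict between two peptidoforms
#'
#' Convenience wrapper for a single comparison; see [ambiguity_classes()].
#'
#' @param a,b Peptidoforms of the same window and channel.
#' @param tol_ppm Mass tolerance in ppm.
#' @param mods Modification table.
#' @return One of \code{"indistinguishable"}, \code{"mass_only_distinct"},
#'   \code{"distinct"}.
#' @export
ambiguity_verdict <- function(a, b, tol_ppm = 10, mods = mod_table()) {
  res <- ambiguity_classes(list(a, b), tol_ppm, mods)
  res$pairs$verdict[1]
}
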