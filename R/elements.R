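#' Monoisotopic element masses
#'
#' Returns the table of monoisotopic atomic masses (in Da) used throughout the
#' package for computing residue, modification and peptidoform masses.
#' Values are CODATA/IUPAC monoisotopic masses to at least six decimal places.
#' Heavy isotopes are carried as separate symbols so that isotope labels
#' (deuterated anhydrides, Arg10) can be tracked independently of the light
#' backbone: \code{"2H"} (deuterium), \code{"13C"} and \code{"15N"}.
#'
#' @return Named numeric vector mapping element symbol to monoisotopic mass.
#'   The vector is a fresh copy on every call; the reference values cannot be
#'   altered by callers.
#' @examples
#' element_masses()[["2H"]] - element_masses()[["H"]]  # ~1.00628 Da
#' @export
element_masses <- function() {
  c(
    H     = 1.00782503207,
    C     = 12.0,
    N     = 14.0030740048,
    O     = 15.9949146196,
    S     = 31.97207100,
    `2H`  = 2.0141017778,
    `13C` = 13.0033548378,
    `15N` = 15.0001088982
  )
}

# Residue (amino acid minus water) elemental compositions for the 20
# standard amino acids, as named integer vectors over C/H/N/O/S.
aa_compositions <- function() {
  list(
    G = c(C = 2L,  H = 3L,  N = 1L, O = 1L),
    A = c(C = 3L,  H = 5L,  N = 1L, O = 1L),
    S = c(C = 3L,  H = 5L,  N = 1L, O = 2L),
    P = c(C = 5L,  H = 7L,  N = 1L, O = 1L),
    V = c(C = 5L,  H = 9L,  N = 1L, O = 1L),
    T = c(C = 4L,  H = 7L,  N = 1L, O = 2L),
    C = c(C = 3L,  H = 5L,  N = 1L, O = 1L, S = 1L),
    L = c(C = 6L,  H = 11L, N = 1L, O = 1L),
    I = c(C = 6L,  H = 11L, N = 1L, O = 1L),
    N = c(C = 4L,  H = 6L,  N = 2L, O = 2L),
    D = c(C = 4L,  H = 5L,  N = 1L, O = 3L),
    Q = c(C = 5L,  H = 8L,  N = 2L, O = 2L),
    K = c(C = 6L,  H = 12L, N = 2L, O = 1L),
    E = c(C = 5L,  H = 7L,  N = 1L, O = 3L),
    M = c(C = 5L,  H = 9L,  N = 1L, O = 1L, S = 1L),
    H = c(C = 6L,  H = 7L,  N = 3L, O = 1L),
    F = c(C = 9L,  H = 9L,  N = 1L, O = 1L),
    R = c(C = 6L,  H = 12L, N = 4L, O = 1L),
    Y = c(C = 9L,  H = 9L,  N = 1L, O = 2L),
    W = c(C = 11L, H = 10L, N = 2L, O = 1L)
  )
}

water_composition <- function() c(H = 2L, O = 1L)

#' Mass of an elemental composition
#'
#' @param composition Named numeric vector of signed element counts, e.g.
#'   \code{c(C = 3, H = 4, O = 1)} for a propionyl group. Negative counts
#'   express substitutions (a D3-acetyl group is \code{C2 + 2H3 - H1 + O1}).
#' @param elements Element mass table, as returned by [element_masses()].
#' @return Monoisotopic mass in Da (numeric scalar).
#' @export
composition_mass <- function(composition, elements = element_masses()) {
  if (length(composition) == 0) return(0)
  syms <- names(composition)
  if (is.null(syms) || any(!nzchar(syms)))
    stop("composition must be a named vector of element counts")
  unknown <- setdiff(syms, names(elements))
  if (length(unknown) > 0)
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  sum(composition * elements[syms])
}

# Sum any number of named count vectors into one composition, dropping zeros.
combine_compositions <- function(...) {
  parts <- list(...)
  out <- numeric(0)
  for (p in parts) {
    if (length(p) == 0) next
    for (sym in names(p)) out[sym] <- (if (sym %in% names(out)) out[[sym]] else 0) + p[[sym]]
  }
  out <- out[out != 0]
  out[order(names(out))]
}

# Map heavy isotopes onto their light elements. Deuterated labels of the same
# acyl are chromatographically equivalent to the light form, so comparing
# isotope-blind compositions predicts co-elution.
isotope_blind <- function(composition) {
  if (length(composition) == 0) return(numeric(0))
  map <- c(`2H` = "H", `13C` = "C", `15N` = "N")
  syms <- names(composition)
  light <- ifelse(syms %in% names(map), map[syms], syms)
  out <- tapply(as.numeric(composition), light, sum)
  out <- out[out != 0]
  res <- as.numeric(out)
  names(res) <- names(out)
  res[order(names(res))]
}

compositions_equal <- function(a, b) {
  a <- a[a != 0]; b <- b[b != 0]
  if (length(a) != length(b)) return(FALSE)
  a <- a[order(names(a))]; b <- b[order(names(b))]
  identical(names(a), names(b)) && all(a == b)
}
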