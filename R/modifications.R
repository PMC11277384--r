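#' Define a modification
#'
#' A modification is a named mass delta backed by a signed elemental
#' composition, a category (endogenous PTM vs chemical derivatization label)
#' and the residue targets it may occupy. The composition is the source of
#' truth for the mass; \code{printed_delta} is an optional literature value
#' used as a cross-check at construction time.
#'
#' @param name Short modification name (e.g. \code{"pr"}, \code{"chem_d3ac"}).
#' @param composition Named numeric vector of signed element counts.
#' @param category One of \code{"endogenous"}, \code{"chemical_label"}.
#' @param targets Character subset of \code{c("K_free", "K_me1",
#'   "peptide_Nterm", "R_residue", "K_residue")}. Endogenous lysine PTMs use
#'   \code{"K_residue"}; chemical lysine labels use \code{K_free}/\code{K_me1}
#'   only, because chemical acylation occurs on unmodified and
#'   mono-methylated lysines.
#' @param printed_delta Optional reference delta mass in Da; construction
#'   fails if the compositional mass differs by more than \code{tol}.
#' @param tol Cross-check tolerance in Da (default 0.001).
#' @return An object of class \code{mod_spec}.
#' @export
mod_spec <- function(name, composition, category = c("endogenous", "chemical_label"),
                     targets, printed_delta = NA_real_, tol = 0.001) {
  category <- match.arg(category)
  if (length(composition) == 0)
    stop("modification '", name, "': composition must be nonempty")
  valid_targets <- c("K_free", "K_me1", "peptide_Nterm", "R_residue", "K_residue")
  bad <- setdiff(targets, valid_targets)
  if (length(bad) > 0)
    stop("modification '", name, "': invalid target(s) ", paste(bad, collapse = ", "))
  if (category == "chemical_label" && "K_residue" %in% targets)
    stop("modification '", name, "': chemical labels may target only free or ",
         "mono-methylated lysines, N-termini or arginine")
  mass <- composition_mass(composition)
  if (!is.na(printed_delta) && abs(mass - printed_delta) > tol)
    stop("modification '", name, "': compositional mass ", format(mass, digits = 10),
         " differs from printed delta ", printed_delta, " by more than ", tol, " Da")
  structure(
    list(name = name, composition = composition, category = category,
         targets = targets, printed_delta = printed_delta, mass = mass),
    class = "mod_spec"
  )
}

#' @export
print.mod_spec <- function(x, ...) {
  cat(sprintf("<mod_spec> %s (%s): %+0.6f Da on {%s}\n", x$name, x$category,
              x$mass, paste(x$targets, collapse = ",")))
  invisible(x)
}

#' Delta mass of a modification
#'
#' Computes the monoisotopic mass shift of a modification from its elemental
#' composition, e.g. propionyl (+C3 +H4 +O1) gives +56.0262 Da and
#' D5-propionyl (+C3 +2H5 -H1 +O1) gives +61.0576 Da.
#'
#' @param spec A [mod_spec()].
#' @param elements Element mass table ([element_masses()]).
#' @return Mass delta in Da.
#' @export
mod_delta_mass <- function(spec, elements = element_masses()) {
  stopifnot(inherits(spec, "mod_spec"))
  composition_mass(spec$composition, elements)
}

#' Built-in modification table
#'
#' The full set of endogenous histone PTMs and chemical derivatization labels
#' the package knows about, each backed by an elemental composition and
#' cross-checked at load against the commonly printed delta mass:
#' methylations (me1/me2/me3), acetylation (ac) and the short-chain acylations
#' propionyl (pr), butyryl (bu), crotonyl (cr), formyl (fo), malonyl (ma),
#' succinyl (su), glutaryl (gl), 2-hydroxy(iso)butyryl (hib) and lactyl (la);
#' plus the chemical labels: propionyl, D5-propionyl and D3-acetyl on lysine,
#' phenyl isocyanate (PIC) and D5-propionyl on peptide N-termini, and the
#' Arg10 heavy-channel label (13C6 15N4) on arginine.
#'
#' Deuterated labels are expressed as substitutions (D3-acetyl is
#' acetyl + 3 x (2H - H)), so the heavy-vs-light offsets fall out of the
#' compositions: D5-propionyl - propionyl = 5.0314 Da (nominal 5) and
#' D3-acetyl - acetyl = 3.0188 Da (nominal 3).
#'
#' @return Named list of [mod_spec()] objects.
#' @export
mod_table <- function() {
  K <- "K_residue"
  endo <- list(
    mod_spec("me1", c(C = 1, H = 2),               "endogenous", K, 14.0157),
    mod_spec("me2", c(C = 2, H = 4),               "endogenous", K, 28.031),
    mod_spec("me3", c(C = 3, H = 6),               "endogenous", K, 42.046),
    mod_spec("ac",  c(C = 2, H = 2, O = 1),        "endogenous", K, 42.010),
    mod_spec("pr",  c(C = 3, H = 4, O = 1),        "endogenous", K, 56.0262),
    mod_spec("bu",  c(C = 4, H = 6, O = 1),        "endogenous", K, 70.0422),
    mod_spec("cr",  c(C = 4, H = 4, O = 1),        "endogenous", K, 68.0262),
    mod_spec("fo",  c(C = 1, O = 1),               "endogenous", K, 27.9949),
    mod_spec("ma",  c(C = 3, H = 2, O = 3),        "endogenous", K, 86.0004),
    mod_spec("su",  c(C = 4, H = 4, O = 3),        "endogenous", K, 100.0160),
    mod_spec("gl",  c(C = 5, H = 6, O = 3),        "endogenous", K, 114.031694),
    mod_spec("hib", c(C = 4, H = 6, O = 2),        "endogenous", K, 86.0368),
    mod_spec("la",  c(C = 3, H = 4, O = 2),        "endogenous", K, 72.021129)
  )
  chem <- list(
    mod_spec("chem_pr",       c(C = 3, H = 4, O = 1),            "chemical_label",
             c("K_free", "K_me1"), 56.0262),
    mod_spec("chem_d5pr",     c(C = 3, `2H` = 5, H = -1, O = 1), "chemical_label",
             c("K_free", "K_me1"), 61.0576),
    mod_spec("chem_d3ac",     c(C = 2, `2H` = 3, H = -1, O = 1), "chemical_label",
             c("K_free", "K_me1"), 45.0294),
    mod_spec("pic",           c(C = 7, H = 5, N = 1, O = 1),     "chemical_label",
             "peptide_Nterm", 119.0371),
    mod_spec("nterm_d5pr",    c(C = 3, `2H` = 5, H = -1, O = 1), "chemical_label",
             "peptide_Nterm", 61.0576),
    mod_spec("arg10",         c(`13C` = 6, C = -6, `15N` = 4, N = -4),
             "chemical_label", "R_residue", 10.008269)
  )
  mods <- c(endo, chem)
  names(mods) <- vapply(mods, function(m) m$name, character(1))
  mods
}

# Endogenous side-chain states that block the chemical lysine label:
# any acyl occupies the epsilon-amine, and di/tri-methylation leaves no
# proton to acylate. Free and me1 lysines receive the label.
blocking_states <- function() {
  c("me2", "me3", "ac", "pr", "bu", "cr", "fo", "ma", "su", "gl", "hib", "la")
}
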