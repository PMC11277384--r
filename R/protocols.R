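#' Derivatization protocols
#'
#' Constructs one of the four in-gel derivatization schemes used for
#' ArgC-like histone digestion. Each protocol names the chemical label placed
#' on free and mono-methylated lysine side chains (first derivatization
#' round, before trypsin), the label placed on every peptide N-terminus
#' (second round, after digestion), and the heavy-channel residue label used
#' for the super-SILAC spike-in (Arg10, +10.008269 Da on R).
#'
#' \describe{
#'   \item{PRO-PIC}{propionyl on K, phenyl isocyanate on N-termini. The
#'     chemical propionyl is identical in mass and composition to endogenous
#'     propionylation, which therefore cannot be distinguished.}
#'   \item{D5PRO-PIC}{D5-propionyl on K, PIC on N-termini; endogenous
#'     propionylation sits 5.0314 Da (nominal 5) below the label.}
#'   \item{D3Ac-PIC}{D3-acetyl on K, PIC on N-termini; endogenous acetylation
#'     sits 3.0188 Da (nominal 3) below the label and endogenous
#'     propionylation is 10.9968 Da away.}
#'   \item{D5PRO-D5PRO}{D5-propionyl on both K and N-termini.}
#' }
#'
#' @param name Protocol name, one of \code{"PRO-PIC"}, \code{"D5PRO-PIC"},
#'   \code{"D3Ac-PIC"}, \code{"D5PRO-D5PRO"}.
#' @param mods Modification table ([mod_table()]).
#' @return An object of class \code{protocol_spec} with elements
#'   \code{name}, \code{lysine_label}, \code{nterm_label}, \code{heavy_label}.
#' @examples
#' p <- protocol_spec("D3Ac-PIC")
#' p$lysine_label$mass  # 45.0294
#' @export
protocol_spec <- function(name = c("PRO-PIC", "D5PRO-PIC", "D3Ac-PIC", "D5PRO-D5PRO"),
                          mods = mod_table()) {
  name <- match.arg(name)
  lys <- switch(name,
    "PRO-PIC"     = mods$chem_pr,
    "D5PRO-PIC"   = mods$chem_d5pr,
    "D3Ac-PIC"    = mods$chem_d3ac,
    "D5PRO-D5PRO" = mods$chem_d5pr
  )
  nterm <- switch(name,
    "D5PRO-D5PRO" = mods$nterm_d5pr,
    mods$pic
  )
  structure(
    list(name = name, lysine_label = lys, nterm_label = nterm,
         heavy_label = mods$arg10),
    class = "protocol_spec"
  )
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf("<protocol_spec> %s: K<-%s (%+0.4f), Nterm<-%s (%+0.4f), heavy %s\n",
              x$name, x$lysine_label$name, x$lysine_label$mass,
              x$nterm_label$name, x$nterm_label$mass, x$heavy_label$name))
  invisible(x)
}

#' All four protocol names
#' @return Character vector of the supported protocol names.
#' @export
protocol_names <- function() c("PRO-PIC", "D5PRO-PIC", "D3Ac-PIC", "D5PRO-D5PRO")
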