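#' Apply a derivatization protocol to a peptide
#'
#' Builds a peptidoform: the peptide window with its positioned endogenous
#' modifications plus the chemical labels the protocol deposits. The rules
#' follow the chemistry of anhydride derivatization: chemical acylation
#' occurs on unmodified and mono-methylated lysines, so every free or me1
#' lysine gains exactly one chemical lysine label (me1 is retained alongside
#' the label), while a lysine bearing any endogenous acyl (ac, pr, bu, ...)
#' or me2/me3 is blocked and gains nothing. Every peptide N-terminus
#' (including a protein N-terminus) gains exactly one N-terminal label. The
#' heavy channel additionally carries the Arg10 label on every arginine.
#'
#' @param window A [peptide_window()].
#' @param endogenous Named character vector of endogenous modifications:
#'   names are 1-based protein positions, values are modification names from
#'   [mod_table()] (e.g. \code{c("14" = "ac")}). Empty or \code{NULL} for the
#'   unmodified peptide.
#' @param protocol A [protocol_spec()].
#' @param channel \code{"light"} or \code{"heavy"}.
#' @param mods Modification table.
#' @return Object of class \code{peptidoform}: the window, the endogenous
#'   modifications, the protocol-applied chemical labels (named character
#'   vector position -> label name, with \code{"0"} for the N-terminus), the
#'   channel and the protocol name.
#' @examples
#' w <- peptide_window("H3", 9, 17, "KSTGGKAPR")
#' apply_protocol(w, c("14" = "ac"), protocol_spec("D3Ac-PIC"))
#' @export
apply_protocol <- function(window, endogenous = NULL,
                           protocol = protocol_spec("PRO-PIC"),
                           channel = c("light", "heavy"),
                           mods = mod_table()) {
  stopifnot(inherits(window, "peptide_window"), inherits(protocol, "protocol_spec"))
  channel <- match.arg(channel)
  endo <- endogenous
  if (is.null(endo)) endo <- character(0)
  if (length(endo) > 0) {
    pos <- as.integer(names(endo))
    if (anyNA(pos)) stop("endogenous modification positions must be named by protein position")
    if (any(pos < window$start | pos > window$end))
      stop("endogenous modification position outside window ",
           window$start, "-", window$end)
    if (anyDuplicated(pos))
      stop("more than one endogenous side-chain state on one residue")
    chars <- strsplit(window$sequence, "")[[1]]
    for (i in seq_along(endo)) {
      mname <- endo[[i]]
      if (!mname %in% names(mods)) stop("unknown modification '", mname, "'")
      m <- mods[[mname]]
      if (m$category != "endogenous")
        stop("'", mname, "' is a chemical label, not an endogenous modification")
      res <- chars[pos[i] - window$start + 1]
      if ("K_residue" %in% m$targets && res != "K")
        stop("endogenous '", mname, "' placed on ", res, pos[i],
             " but targets lysine only")
    }
    endo <- endo[order(pos)]
  }
  # chemical labels: every free or me1 K gets the lysine label
  chars <- strsplit(window$sequence, "")[[1]]
  kpos <- window$start - 1L + which(chars == "K")
  labels <- character(0)
  block <- blocking_states()
  for (p in kpos) {
    state <- if (as.character(p) %in% names(endo)) endo[[as.character(p)]] else "free"
    if (!(state %in% block)) labels[as.character(p)] <- protocol$lysine_label$name
  }
  labels["0"] <- protocol$nterm_label$name  # "0" = peptide N-terminus
  if (channel == "heavy") {
    rpos <- window$start - 1L + which(chars == "R")
    for (p in rpos) labels[paste0("R", p)] <- protocol$heavy_label$name
  }
  structure(
    list(window = window, endogenous = endo, labels = labels,
         channel = channel, protocol = protocol$name),
    class = "peptidoform"
  )
}

#' Total elemental composition of a peptidoform
#'
#' Residue compositions plus water plus every endogenous modification and
#' chemical label (heavy-isotope atoms kept distinct).
#'
#' @param pf A [apply_protocol()] peptidoform.
#' @param mods Modification table.
#' @return Named numeric vector of element counts.
#' @export
peptidoform_composition <- function(pf, mods = mod_table()) {
  stopifnot(inherits(pf, "peptidoform"))
  aacomp <- aa_compositions()
  chars <- strsplit(pf$window$sequence, "")[[1]]
  unknown <- which(!(chars %in% names(aacomp)))
  if (length(unknown) > 0)
    stop("unknown residue '", chars[unknown[1]], "' at position ",
         pf$window$start + unknown[1] - 1L)
  parts <- c(unname(aacomp[chars]), list(water_composition()),
             lapply(unname(c(pf$endogenous, pf$labels)), function(nm) mods[[nm]]$composition))
  do.call(combine_compositions, parts)
}

#' Monoisotopic mass of a peptidoform
#'
#' Standard peptide mass bookkeeping: sum of residue masses plus water plus
#' all modification deltas. A heavy-channel form exceeds its light
#' counterpart by 10.008269 Da per arginine (the Arg10 label).
#'
#' @inheritParams peptidoform_composition
#' @param elements Element mass table.
#' @return Monoisotopic mass in Da.
#' @export
peptidoform_mass <- function(pf, mods = mod_table(), elements = element_masses()) {
  composition_mass(peptidoform_composition(pf, mods), elements)
}

#' Canonical peptidoform key
#'
#' A readable identifier like \code{"H3 9-17 K9me1K14ac"} (\code{"unmod"}
#' when no endogenous modification is present). Chemical labels are implied
#' by the protocol and are not part of the key.
#'
#' @param pf A peptidoform.
#' @return Character scalar.
#' @export
peptidoform_key <- function(pf) {
  paste(window_id(pf$window), mods_string(pf$endogenous))
}

# "K9me1K14ac" notation for a positioned endogenous mod set; "unmod" if empty
mods_string <- function(endo) {
  if (length(endo) == 0) return("unmod")
  pos <- as.integer(names(endo))
  o <- order(pos)
  paste0("K", pos[o], unname(endo)[o], collapse = "")
}

# inverse of mods_string
parse_mods_string <- function(s) {
  if (is.na(s) || s == "" || s == "unmod") return(character(0))
  m <- gregexpr("K([0-9]+)([a-z0-9]+?)(?=K[0-9]|$)", s, perl = TRUE)[[1]]
  if (m[1] == -1) stop("malformed modification string: '", s, "'")
  parts <- regmatches(s, gregexpr("K([0-9]+)([a-z0-9]+?)(?=K[0-9]|$)", s, perl = TRUE))[[1]]
  pos <- sub("^K([0-9]+).*$", "\\1", parts)
  nm <- sub("^K[0-9]+", "", parts)
  stats::setNames(nm, pos)
}

#' @export
print.peptidoform <- function(x, ...) {
  cat(sprintf("<peptidoform> %s [%s, %s] %0.4f Da\n", peptidoform_key(x),
              x$protocol, x$channel, peptidoform_mass(x)))
  invisible(x)
}

#' Enumerate peptidoforms of a window
#'
#' Cartesian product of per-site endogenous states, with the protocol applied
#' to each combination. Used as the search space for ambiguity analysis and
#' by the data simulator.
#'
#' @param window A [peptide_window()].
#' @param site_states Named list: names are protein positions (of lysines in
#'   the window), values are character vectors of states drawn from
#'   \code{"free"} plus modification names (e.g.
#'   \code{list("9" = c("free", "me1", "pr"))}).
#' @param protocol A [protocol_spec()].
#' @param channel \code{"light"} or \code{"heavy"}.
#' @param cap Maximum number of forms to enumerate; exceeding it is an error.
#' @param mods Modification table.
#' @return List of peptidoforms of length \code{prod(lengths(site_states))}.
#' @export
enumerate_forms <- function(window, site_states, protocol,
                            channel = "light", cap = 10000, mods = mod_table()) {
  stopifnot(inherits(window, "peptide_window"))
  if (length(site_states) > 0) {
    pos <- as.integer(names(site_states))
    if (anyNA(pos) || any(pos < window$start | pos > window$end))
      stop("site_states positions must lie inside the window")
  }
  n_forms <- prod(vapply(site_states, length, integer(1)))
  if (n_forms > cap)
    stop("search space too large: ", n_forms, " forms exceeds cap ", cap)
  grid <- expand.grid(site_states, stringsAsFactors = FALSE)
  if (nrow(grid) == 0)
    grid <- data.frame(row.names = 1)  # single unmodified combination
  lapply(seq_len(max(1L, nrow(grid))), function(i) {
    endo <- character(0)
    for (p in names(site_states)) {
      st <- grid[i, p]
      if (st != "free") endo[p] <- st
    }
    apply_protocol(window, endo, protocol, channel, mods)
  })
}
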