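# Shared fixtures and independent oracles used across test files.

h3_n50 <- "ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHRYRPGTVALR"

w_h3_917 <- peptide_window("H3", 9, 17, "KSTGGKAPR")
w_h3_1826 <- peptide_window("H3", 18, 26, "KQLATKAAR")
w_h3_2740 <- peptide_window("H3", 27, 40, "KSAPATGGVKKPHR")
w_h4_tail <- peptide_window("H4", 4, 17, "GKGGKGLGKGGAKR")

# Brute-force digestion oracle: enumerate every (start, end) substring and
# keep those whose boundaries are legal cleavage points, whose internal
# missed-cleavage count is within bounds, and whose length passes.
brute_digest <- function(sequence, max_missed, min_length, proline_rule = TRUE) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  legal_cut <- function(i) {
    # cleavage after position i
    if (i < 1 || i >= n) return(FALSE)
    chars[i] == "R" && (!proline_rule || chars[i + 1] != "P")
  }
  rows <- list()
  for (s in 1:n) {
    for (e in s:n) {
      if (e - s + 1 < min_length) next
      if (!(s == 1 || legal_cut(s - 1))) next
      if (!(e == n || legal_cut(e))) next
      internal <- if (e > s) sum(vapply(s:(e - 1), legal_cut, logical(1))) else 0
      if (internal > max_missed) next
      rows[[length(rows) + 1]] <- data.frame(
        start = s, end = e, sequence = substr(sequence, s, e),
        missed = internal, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      sequence = character(0), missed = integer(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_sequence <- function(len) {
  paste(sample(names(histoneacyl:::aa_compositions()), len, replace = TRUE),
        collapse = "")
}

# Minimal PSM row constructor for merge/filter tests
psm_row <- function(raw = "f1", scan = 1, seq = "KSTGGKAPR", mods = "unmod",
                    score = 100, loc = NA_real_, decoy = FALSE,
                    contaminant = FALSE, search = "base", channel = "light") {
  data.frame(RawFile = raw, Scan = scan, Sequence = seq, Modifications = mods,
             Score = score, LocalizationProb = loc, Decoy = decoy,
             Contaminant = contaminant, SearchId = search, Channel = channel,
             stringsAsFactors = FALSE)
}
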