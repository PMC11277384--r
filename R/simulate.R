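#' Built-in histone sequences
#'
#' N-terminal regions of canonical human histones H3, H4, H2A (type 1) and
#' H2B (type 1), the regions carrying essentially all of the modification
#' sites this workflow quantifies. Full proteomes are unnecessary for
#' testing the pipeline.
#'
#' @return Named character vector of protein sequences.
#' @export
builtin_histones <- function() {
  c(
    H3  = "ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHRYRPGTVALREIRR",
    H4  = "SGRGKGGKGLGKGGAKRHRKVLRDNIQGITKPAIRRLARRGGVKRISGLIYEETR",
    H2A = "SGRGKQGGKARAKAKTRSSRAGLQFPVGRVHRLLRKGNYAERVGAGAPVYLAAVLEYLTAEILELAGNAARDNKKTRIIPRHLQLAIR",
    H2B = "PEPAKSAPAPKKGSKKAVTKAQKKDGKKRKRSRKESYSVYVYKVLKQVHPDTGISSKAMGIMNSFVNDIFERIAGEASR"
  )
}

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a derivatization
#' protocol, a number of ground-truthed peptidoforms drawn from the
#' enumerated modification space of the built-in histone windows, a
#' condition/replicate design, a heavy super-SILAC channel covering a
#' fraction of the peptidoforms, multiplicative lognormal area noise,
#' record-level missingness, same-spectrum competitor assignments across
#' parallel searches, and score / localization-probability distributions on
#' either side of the confidence filters.
#'
#' @param seed RNG seed (mandatory; all randomness flows from it).
#' @param protocol Protocol name (default \code{"D3Ac-PIC"}, the protocol of
#'   choice for propionylation/butyrylation work).
#' @param n_peptidoforms Number of simulated peptidoforms (default 50).
#' @param n_conditions,n_replicates Design size (defaults 3 and 4).
#' @param cv Coefficient of variation of the multiplicative lognormal area
#'   noise (default 0.2).
#' @param coverage Probability that a peptidoform is represented in the heavy
#'   spike-in (default 0.7, reproducing the observed ~30\% of sites without a
#'   spike-in counterpart).
#' @param ambiguity_rate Fraction of spectra that also receive a competitor
#'   assignment in another search (default 0.2).
#' @param missing_rate Probability that a (peptidoform, sample) XIC record is
#'   absent (default 0.05).
#' @param resolved_fail_rate Probability that a peptidoform's chromatographic
#'   peak is not clearly resolved (default 0.05).
#' @param shared_profiles If \code{TRUE}, all conditions share one true \%RA
#'   profile (no true differences; for null / type-I studies). Default
#'   \code{FALSE}.
#' @param score_true,score_competitor Mean and sd of the (truncated-at-0)
#'   normal score distributions for true and competitor assignments;
#'   defaults \code{c(120, 25)} and \code{c(60, 20)}, placing mass on both
#'   sides of the score-40 filter.
#' @param loc_shape Beta shape parameters for localization probabilities of
#'   true assignments (default \code{c(12, 1)}: most above 0.75, some below).
#' @param n_decoys Decoy/contaminant rows added to exercise the filters
#'   (default 5).
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(seed, protocol = "D3Ac-PIC", n_peptidoforms = 50,
                       n_conditions = 3, n_replicates = 4, cv = 0.2,
                       coverage = 0.7, ambiguity_rate = 0.2,
                       missing_rate = 0.05, resolved_fail_rate = 0.05,
                       shared_profiles = FALSE,
                       score_true = c(120, 25), score_competitor = c(60, 20),
                       loc_shape = c(12, 1), n_decoys = 5) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  for (p in c(coverage, ambiguity_rate, missing_rate, resolved_fail_rate))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (cv < 0) stop("cv must be >= 0")
  if (n_peptidoforms < 1 || n_conditions < 1 || n_replicates < 1)
    stop("design sizes must be >= 1")
  protocol <- match.arg(protocol, protocol_names())
  structure(list(seed = as.integer(seed), protocol = protocol,
                 n_peptidoforms = n_peptidoforms, n_conditions = n_conditions,
                 n_replicates = n_replicates, cv = cv, coverage = coverage,
                 ambiguity_rate = ambiguity_rate, missing_rate = missing_rate,
                 resolved_fail_rate = resolved_fail_rate,
                 shared_profiles = shared_profiles, score_true = score_true,
                 score_competitor = score_competitor, loc_shape = loc_shape,
                 n_decoys = n_decoys),
            class = "sim_config")
}

# Enumerate the candidate peptidoform space: every window of the built-in
# histones with 1-4 lysines, each lysine in state free/me1/ac/pr/bu.
candidate_forms <- function(max_k = 4) {
  states <- c("free", "me1", "ac", "pr", "bu")
  seqs <- builtin_histones()
  out <- list()
  for (prot in names(seqs)) {
    wins <- digest_protein(prot, seqs[[prot]], max_missed = 0, min_length = 4)
    for (w in wins) {
      chars <- strsplit(w$sequence, "")[[1]]
      kpos <- w$start - 1L + which(chars == "K")
      if (length(kpos) < 1 || length(kpos) > max_k) next
      grid <- expand.grid(rep(list(states), length(kpos)),
                          stringsAsFactors = FALSE)
      for (i in seq_len(nrow(grid))) {
        endo <- character(0)
        for (j in seq_along(kpos)) {
          if (grid[i, j] != "free") endo[as.character(kpos[j])] <- grid[i, j]
        }
        key <- paste(window_id(w), mods_string(endo))
        out[[key]] <- list(window = w, endo = endo,
                           mods = mods_string(endo),
                           category = mod_category(mods_string(endo)))
      }
    }
  }
  out
}

# map a modification category to the single-acylation search that finds it:
# each parallel search covers one acylation plus the base methyl/acetyl set
search_of_category <- function(category) {
  ifelse(category %in% c("pr", "bu", "other_acyl"), category, "base")
}

trunc_norm <- function(n, mean, sd) pmax(0, stats::rnorm(n, mean, sd))

#' Simulate a ground-truthed dataset
#'
#' Generates the three input tables the pipeline consumes (per-search PSM
#' tables, an XIC area table, a sample-design table) together with the
#' ground truth they were drawn from. Deterministic given the seed. Each true
#' acylated peptidoform appears in the PSM table of its own acylation's
#' search; a configurable fraction of spectra additionally receives a
#' lower-scoring competitor assignment in a different search (see
#' [inject_ambiguity()]). XIC areas are (group total) x (true \%RA) x
#' lognormal noise with the configured CV; the heavy channel draws from the
#' spike-in profile for the covered subset of peptidoforms.
#'
#' @param config A [sim_config()].
#' @return List with \code{psm_runs} (named list of PSM data.frames, one per
#'   search), \code{xic}, \code{design}, \code{truth} (list: \code{ra} true
#'   per-condition \%RA and log2 L/H, \code{assignments} true per-spectrum
#'   assignment, \code{forms} per-peptidoform coverage/resolved flags) and
#'   \code{config}.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  protocol <- protocol_spec(config$protocol)
  pool <- candidate_forms()
  if (config$n_peptidoforms > length(pool))
    stop("n_peptidoforms exceeds the enumerable form space (",
         length(pool), ")")
  picked <- sort(sample(names(pool), config$n_peptidoforms))
  forms <- pool[picked]

  windows <- vapply(forms, function(f) window_id(f$window), character(1))
  mods <- vapply(forms, function(f) f$mods, character(1))
  seqs <- vapply(forms, function(f) f$window$sequence, character(1))
  category <- vapply(forms, function(f) f$category, character(1))
  searches <- search_of_category(category)
  keys <- names(forms)

  conditions <- paste0("cond", seq_len(config$n_conditions))
  design <- expand.grid(Replicate = seq_len(config$n_replicates),
                        Condition = conditions, stringsAsFactors = FALSE)
  design$Sample <- paste0(design$Condition, "_R", design$Replicate)
  design$Treated <- design$Condition != conditions[1]
  design$Matched <- paste0("pair", design$Replicate)
  design <- design[, c("Sample", "Condition", "Replicate", "Treated", "Matched")]

  # per-peptidoform flags
  covered <- stats::rbinom(length(keys), 1, config$coverage) == 1
  resolved <- stats::rbinom(length(keys), 1, 1 - config$resolved_fail_rate) == 1

  # true profiles: per window group, per condition, a Dirichlet-like draw
  # normalized to 100; the heavy spike-in has one profile over covered forms
  ra <- NULL
  heavy_ra <- rep(NA_real_, length(keys))
  light_ra <- matrix(NA_real_, length(keys), length(conditions),
                     dimnames = list(keys, conditions))
  for (w in unique(windows)) {
    idx <- which(windows == w)
    base_profile <- stats::rgamma(length(idx), shape = 2) + 0.05
    for (ci in seq_along(conditions)) {
      p <- if (config$shared_profiles) base_profile
           else stats::rgamma(length(idx), shape = 2) + 0.05
      light_ra[idx, ci] <- 100 * p / sum(p)
    }
    cov_idx <- idx[covered[idx]]
    if (length(cov_idx) > 0) {
      q <- stats::rgamma(length(cov_idx), shape = 2) + 0.05
      heavy_ra[cov_idx] <- 100 * q / sum(q)
    }
  }
  truth_ra <- do.call(rbind, lapply(seq_along(conditions), function(ci) {
    data.frame(Peptidoform = keys, Window = windows,
               Condition = conditions[ci],
               LightRA = light_ra[, ci], HeavyRA = heavy_ra,
               Log2LH = log2(light_ra[, ci] / heavy_ra),
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  sigma <- sqrt(log(1 + config$cv^2))
  noise <- function(n) exp(stats::rnorm(n, -sigma^2 / 2, sigma))

  # XIC records
  xic_rows <- list()
  for (si in seq_len(nrow(design))) {
    smp <- design$Sample[si]
    ci <- match(design$Condition[si], conditions)
    for (w in unique(windows)) {
      idx <- which(windows == w)
      t_light <- 1e9 * stats::runif(1, 0.5, 2)   # loading varies per sample
      t_heavy <- 1e9 * stats::runif(1, 0.5, 2)
      present <- stats::runif(length(idx)) >= config$missing_rate
      for (k in seq_along(idx)) {
        if (!present[k]) next
        i <- idx[k]
        la <- t_light * light_ra[i, ci] / 100 * noise(1)
        ha <- if (covered[i]) t_heavy * heavy_ra[i] / 100 * noise(1) else NA_real_
        xic_rows[[length(xic_rows) + 1L]] <- data.frame(
          Peptidoform = keys[i], Window = windows[i], Sequence = seqs[i],
          Mods = mods[i], Sample = smp, LightArea = la, HeavyArea = ha,
          ResolvedPeak = resolved[i], stringsAsFactors = FALSE)
      }
    }
  }
  xic <- do.call(rbind, xic_rows)
  rownames(xic) <- NULL

  # PSM rows: one light PSM per observed (peptidoform, sample); heavy PSMs
  # for covered peptidoforms (the spike-in is present in every sample)
  n_l <- nrow(xic)
  psm <- data.frame(
    RawFile = xic$Sample, Scan = seq_len(n_l), Sequence = xic$Sequence,
    Modifications = xic$Mods, Score = trunc_norm(n_l, config$score_true[1],
                                                 config$score_true[2]),
    LocalizationProb = ifelse(xic$Mods == "unmod", NA_real_,
                              stats::rbeta(n_l, config$loc_shape[1],
                                           config$loc_shape[2])),
    Decoy = FALSE, Contaminant = FALSE,
    SearchId = searches[match(xic$Peptidoform, keys)],
    Channel = "light", stringsAsFactors = FALSE)
  heavy_obs <- !is.na(xic$HeavyArea)
  if (any(heavy_obs)) {
    hv <- xic[heavy_obs, , drop = FALSE]
    n_h <- nrow(hv)
    psm_h <- data.frame(
      RawFile = hv$Sample, Scan = n_l + seq_len(n_h), Sequence = hv$Sequence,
      Modifications = hv$Mods, Score = trunc_norm(n_h, config$score_true[1],
                                                  config$score_true[2]),
      LocalizationProb = ifelse(hv$Mods == "unmod", NA_real_,
                                stats::rbeta(n_h, config$loc_shape[1],
                                             config$loc_shape[2])),
      Decoy = FALSE, Contaminant = FALSE,
      SearchId = searches[match(hv$Peptidoform, keys)],
      Channel = "heavy", stringsAsFactors = FALSE)
    psm <- rbind(psm, psm_h)
  }
  truth_assign <- psm[psm$Channel == "light",
                      c("RawFile", "Scan", "Sequence", "Modifications")]
  rownames(truth_assign) <- NULL

  # decoys (to be removed by the confidence filter)
  if (config$n_decoys > 0) {
    psm <- rbind(psm, data.frame(
      RawFile = sample(design$Sample, config$n_decoys, replace = TRUE),
      Scan = max(psm$Scan) + seq_len(config$n_decoys),
      Sequence = "REVERSED", Modifications = "unmod",
      Score = trunc_norm(config$n_decoys, config$score_true[1],
                         config$score_true[2]),
      LocalizationProb = NA_real_, Decoy = TRUE, Contaminant = FALSE,
      SearchId = "base", Channel = "light", stringsAsFactors = FALSE))
  }

  psm <- inject_ambiguity(psm, config$ambiguity_rate, pool, config)

  runs <- split(psm, psm$SearchId)
  truth <- list(
    ra = truth_ra,
    assignments = truth_assign,
    forms = data.frame(Peptidoform = keys, Window = windows,
                       Sequence = seqs, Mods = mods, Category = category,
                       Search = searches, Covered = covered,
                       Resolved = resolved, stringsAsFactors = FALSE,
                       row.names = NULL)
  )
  list(psm_runs = runs, xic = xic, design = design, truth = truth,
       config = config)
}

#' Inject same-spectrum competitor assignments
#'
#' Emulates the ambiguity the parallel single-acylation searches create: a
#' selected fraction of true light-channel spectra is duplicated into a
#' different search with an alternative assignment (another enumerable
#' peptidoform of the same window, preferentially from a different search)
#' drawn with a lower-mean score distribution, so the score-based merge is
#' exercised with known truth.
#'
#' @param psm PSM data.frame (all searches stacked; \code{SearchId} column).
#' @param rate Fraction of true light spectra that receive a competitor.
#' @param pool Candidate-form pool (internal; \code{candidate_forms()}).
#' @param config A [sim_config()] (score/localization distributions).
#' @return PSM data.frame with competitor rows appended.
#' @export
inject_ambiguity <- function(psm, rate, pool = candidate_forms(), config) {
  if (rate == 0) return(psm)
  eligible <- which(psm$Channel == "light" & !psm$Decoy & !psm$Contaminant &
                      psm$Sequence != "REVERSED")
  hit <- eligible[stats::runif(length(eligible)) < rate]
  if (length(hit) == 0) return(psm)
  pool_seq <- vapply(pool, function(f) f$window$sequence, character(1))
  pool_mods <- vapply(pool, function(f) f$mods, character(1))
  pool_search <- search_of_category(
    vapply(pool, function(f) f$category, character(1)))
  comp_rows <- list()
  for (i in hit) {
    cand <- which(pool_seq == psm$Sequence[i] &
                    pool_mods != psm$Modifications[i] &
                    pool_search != psm$SearchId[i])
    if (length(cand) == 0) next
    j <- if (length(cand) == 1) cand else sample(cand, 1)
    comp_rows[[length(comp_rows) + 1L]] <- data.frame(
      RawFile = psm$RawFile[i], Scan = psm$Scan[i],
      Sequence = pool_seq[j], Modifications = pool_mods[j],
      Score = trunc_norm(1, config$score_competitor[1],
                         config$score_competitor[2]),
      LocalizationProb = ifelse(pool_mods[j] == "unmod", NA_real_,
                                stats::rbeta(1, config$loc_shape[1],
                                             config$loc_shape[2])),
      Decoy = FALSE, Contaminant = FALSE, SearchId = pool_search[j],
      Channel = "light", stringsAsFactors = FALSE)
  }
  if (length(comp_rows) == 0) return(psm)
  rbind(psm, do.call(rbind, comp_rows))
}

#' Write a simulated dataset to disk
#'
#' Writes the PSM tables (one TSV per search), the XIC and design tables,
#' the ground-truth tables, the built-in histone FASTA and a JSON manifest
#' carrying the configuration and its hash (the hash changes iff the
#' configuration changes).
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_fixtures <- function(sim, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", dir)
  }
  files <- character(0)
  for (s in names(sim$psm_runs)) {
    f <- file.path(dir, paste0("psm_", s, ".tsv"))
    write_tsv(sim$psm_runs[[s]], f)
    files <- c(files, basename(f))
  }
  write_tsv(sim$xic, file.path(dir, "xic.tsv"))
  write_tsv(sim$design, file.path(dir, "design.tsv"))
  write_tsv(sim$truth$ra, file.path(dir, "truth_ra.tsv"))
  write_tsv(sim$truth$assignments, file.path(dir, "truth_assignments.tsv"))
  write_tsv(sim$truth$forms, file.path(dir, "truth_forms.tsv"))
  write_fasta(builtin_histones(), file.path(dir, "histones.fasta"))
  files <- c(files, "xic.tsv", "design.tsv", "truth_ra.tsv",
             "truth_assignments.tsv", "truth_forms.tsv", "histones.fasta")
  manifest <- list(config = unclass(sim$config),
                   config_hash = config_hash(sim$config),
                   files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(unclass(config)), collapse = ""), tmp)
  unname(tools::md5sum(tmp))
}
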