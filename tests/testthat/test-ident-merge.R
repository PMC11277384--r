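test_that("merge keeps the highest-scoring assignment per spectrum and logs competitors", {
  r1 <- psm_row(scan = 1, mods = "K13pr", score = 80, loc = 0.9, search = "pr")
  r2 <- psm_row(scan = 1, mods = "K13bu", score = 95, loc = 0.9, search = "bu")
  m <- merge_searches(list(r1, r2))
  expect_equal(nrow(m), 1)
  expect_equal(m$Modifications, "K13bu")
  expect_match(m$Provenance, "discarded:pr")
  # spectrum in one run only is kept unchanged
  r3 <- psm_row(scan = 2, mods = "K13ac", score = 50, search = "base")
  m2 <- merge_searches(list(rbind(r1, r3), r2))
  expect_equal(nrow(m2), 2)
  expect_equal(m2$Modifications[m2$Scan == 2], "K13ac")
})

test_that("identical assignments across runs deduplicate to one row", {
  r1 <- psm_row(scan = 3, mods = "K13pr", score = 70, search = "pr")
  r2 <- psm_row(scan = 3, mods = "K13pr", score = 70, search = "bu")
  m <- merge_searches(list(r1, r2))
  expect_equal(nrow(m), 1)
  expect_false(grepl("discarded", m$Provenance))
})

test_that("merged row count and scores match a brute-force max per spectrum", {
  set.seed(5)
  runs <- lapply(c("pr", "bu", "base"), function(s) {
    scans <- sample(1:100, 80)
    do.call(rbind, lapply(scans, function(sc)
      psm_row(scan = sc, mods = paste0("K13", sample(c("pr", "bu", "me1"), 1)),
              score = round(runif(1, 10, 150), 2), search = s)))
  })
  m <- merge_searches(runs)
  all_rows <- do.call(rbind, runs)
  expect_equal(nrow(m), length(unique(all_rows$Scan)))
  want <- tapply(all_rows$Score, all_rows$Scan, max)
  expect_equal(unname(m$Score[order(m$Scan)]), as.numeric(want[order(as.numeric(names(want)))]))
})

test_that("merge is idempotent and invariant to run order", {
  set.seed(6)
  runs <- lapply(c("pr", "bu"), function(s)
    do.call(rbind, lapply(1:40, function(sc)
      psm_row(scan = sc, mods = paste0("K13", sample(c("pr", "bu"), 1)),
              score = round(runif(1, 10, 150), 2), search = s))))
  m1 <- merge_searches(runs)
  core <- c("RawFile", "Scan", "Sequence", "Modifications", "Score", "SearchId")
  m2 <- merge_searches(m1[, setdiff(names(m1), "Provenance")])
  expect_equal(m1[, core], m2[, core])
  m3 <- merge_searches(rev(runs))
  expect_equal(m1[, core], m3[, core])
})

test_that("equal-score ties break toward fewer modified residues then mod string", {
  r1 <- psm_row(scan = 1, mods = "K9me1K14pr", score = 90, search = "pr")
  r2 <- psm_row(scan = 1, mods = "K9bu", score = 90, search = "bu")
  m <- merge_searches(list(r1, r2))
  expect_equal(m$Modifications, "K9bu")
})

test_that("conflicting assignments inside one run are a malformed input", {
  r <- rbind(psm_row(scan = 1, mods = "K13pr", search = "pr"),
             psm_row(scan = 1, mods = "K13bu", search = "pr"))
  expect_error(merge_searches(list(r)), "malformed run")
})

test_that("confidence filter applies strict thresholds and removes decoys", {
  tab <- rbind(
    psm_row(scan = 1, mods = "K13pr", score = 39.9, loc = 0.99),
    psm_row(scan = 2, mods = "K13pr", score = 40.0, loc = 0.75),
    psm_row(scan = 3, mods = "unmod", score = 200, decoy = TRUE),
    psm_row(scan = 4, mods = "K13pr", score = 120, loc = 0.74),
    psm_row(scan = 5, mods = "unmod", score = 45, loc = NA),
    psm_row(scan = 6, mods = "K13pr", score = 45, loc = NA))
  f <- filter_psms(tab)
  # 39.9 removed (strict <40); boundary 40/0.75 retained; decoy removed;
  # loc 0.74 removed; unmodified passes vacuously; modified without a
  # localization cannot be placed and is removed
  expect_equal(sort(f$Scan), c(2, 5))
  expect_error(filter_psms(tab[, setdiff(names(tab), "Score")]), "Score")
  expect_error(filter_psms(tab, score_min = -1), ">= 0")
})

test_that("raising the score threshold never adds rows (monotone filtering)", {
  set.seed(7)
  tab <- do.call(rbind, lapply(1:50, function(i)
    psm_row(scan = i, mods = "K13pr", score = runif(1, 0, 150),
            loc = runif(1))))
  prev <- Inf
  for (smin in c(0, 20, 40, 80, 120)) {
    n <- nrow(filter_psms(tab, score_min = smin))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("collapse groups PSMs into peptidoforms with per-sample counts", {
  tab <- rbind(
    psm_row(raw = "s1", scan = 1, mods = "K9pr", loc = 0.9, search = "pr"),
    psm_row(raw = "s1", scan = 2, mods = "K9pr", loc = 0.9, search = "pr"),
    psm_row(raw = "s2", scan = 3, mods = "K9pr", loc = 0.9, search = "pr"),
    psm_row(raw = "s2", scan = 4, mods = "K9pr", loc = 0.9, search = "pr"),
    psm_row(raw = "s2", scan = 5, mods = "K9pr", loc = 0.9, search = "pr"),
    psm_row(raw = "s1", scan = 6, mods = "K9bu", loc = 0.9, search = "bu",
            channel = "heavy"))
  ids <- collapse_to_peptidoforms(tab)
  pr <- ids[ids$Modifications == "K9pr", ]
  expect_equal(pr$NSamples, 2)
  expect_equal(pr$SampleCounts, "s1:2,s2:3")
  expect_false(pr$SpikeIn)
  bu <- ids[ids$Modifications == "K9bu", ]
  expect_true(bu$SpikeIn && bu$SpikeInOnly)
})

test_that("modification categories tally as by hand on a mixed fixture", {
  mods <- c("K9pr", "K9me1K14pr", "K9bu", "K9cr", "K9su", "K9ac",
            "K9me1K14ac", "K9me2", "K9me3K14me1", "unmod")
  got <- table(mod_category(mods))
  expect_equal(got[["pr"]], 2)
  expect_equal(got[["bu"]], 1)
  expect_equal(got[["other_acyl"]], 2)
  expect_equal(got[["ac"]], 2)
  expect_equal(got[["methyl"]], 2)
  expect_equal(got[["unmodified"]], 1)
})
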