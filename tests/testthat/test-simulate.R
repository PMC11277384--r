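test_that("simulation is deterministic given the seed", {
  s1 <- simulate_dataset(sim_config(seed = 21, n_peptidoforms = 15))
  s2 <- simulate_dataset(sim_config(seed = 21, n_peptidoforms = 15))
  expect_identical(s1$psm_runs, s2$psm_runs)
  expect_identical(s1$xic, s2$xic)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_dataset(sim_config(seed = 22, n_peptidoforms = 15))
  expect_false(identical(s1$xic, s3$xic))
})

test_that("config validates probabilities, sizes and the mandatory seed", {
  expect_error(sim_config(), "seed is mandatory")
  expect_error(sim_config(seed = 1, coverage = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(seed = 1, cv = -0.1), "cv")
  expect_error(sim_config(seed = 1, n_peptidoforms = 0), "sizes")
})

test_that("true %RA profiles sum to 100 per window group and condition", {
  sim <- simulate_dataset(sim_config(seed = 23, n_peptidoforms = 40))
  tr <- sim$truth$ra
  sums <- tapply(tr$LightRA, paste(tr$Window, tr$Condition), sum)
  expect_equal(as.numeric(sums), rep(100, length(sums)), tolerance = 1e-9)
})

test_that("noiseless, complete data is recovered exactly by the pipeline", {
  sim <- simulate_dataset(sim_config(seed = 24, n_peptidoforms = 25, cv = 0,
                                     missing_rate = 0, coverage = 1,
                                     resolved_fail_rate = 0,
                                     ambiguity_rate = 0))
  res <- run_pipeline(sim$psm_runs, sim$xic, sim$design)
  q <- res$quant
  ra_sums <- tapply(q$LightRA, paste(q$Window, q$Sample), sum, na.rm = TRUE)
  expect_equal(as.numeric(ra_sums), rep(100, length(ra_sums)), tolerance = 1e-9)
  err <- recovery_errors(res$normalized, sim$truth$ra, sim$design)
  expect_gt(nrow(err), 0)
  expect_lt(max(abs(err$Error)), 1e-9)
})

test_that("recovery error decreases monotonically with CV and is 0 at CV=0", {
  meds <- vapply(c(0, 0.1, 0.2), function(cv) {
    sim <- simulate_dataset(sim_config(seed = 25, n_peptidoforms = 30, cv = cv,
                                       missing_rate = 0, coverage = 1,
                                       resolved_fail_rate = 0,
                                       ambiguity_rate = 0))
    res <- run_pipeline(sim$psm_runs, sim$xic, sim$design)
    err <- recovery_errors(res$normalized, sim$truth$ra, sim$design)
    median(abs(err$Error))
  }, numeric(1))
  expect_equal(meds[1], 0, tolerance = 1e-12)
  expect_true(all(diff(meds) > 0))
})

test_that("spike-in coverage drives the quantifiable fraction as expected", {
  cfg <- sim_config(seed = 26, n_peptidoforms = 100, coverage = 0.7,
                    missing_rate = 0, resolved_fail_rate = 0,
                    ambiguity_rate = 0)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$truth$forms), 100)
  n_cov <- sum(sim$truth$forms$Covered)
  # binomial expectation: ~30 of 100 fail the spike-in rule, within 3 SE
  se <- sqrt(100 * 0.7 * 0.3)
  expect_lt(abs(n_cov - 70), 3 * se)
  res <- run_pipeline(sim$psm_runs, sim$xic, sim$design)
  ids <- res$ids
  truth_key <- paste(sim$truth$forms$Sequence, sim$truth$forms$Mods)
  id_key <- paste(ids$Sequence, ids$Modifications)
  covered <- sim$truth$forms$Covered[match(id_key, truth_key)]
  sim_ids <- !is.na(covered)
  # quantifiability rule (2): uncovered peptidoforms are never quantifiable
  expect_true(all(!ids$Quantifiable[sim_ids & !covered]))
})

test_that("ambiguity injection adds competitor rows at the requested rate", {
  psm <- do.call(rbind, lapply(1:50, function(i)
    psm_row(scan = i, seq = "KSTGGKAPR", mods = "K9pr", search = "pr")))
  cfg <- sim_config(seed = 27)
  set.seed(27)
  out0 <- inject_ambiguity(psm, 0, config = cfg)
  expect_identical(out0, psm)
  set.seed(27)
  out1 <- inject_ambiguity(psm, 1, config = cfg)
  added <- nrow(out1) - nrow(psm)
  expect_equal(added, 50)
  comp <- out1[51:nrow(out1), ]
  expect_true(all(comp$SearchId != "pr"))
  expect_true(all(comp$Sequence == "KSTGGKAPR"))
  expect_true(all(comp$Modifications != "K9pr"))
})

test_that("with lower-scoring competitors the merge recovers >=95% of truth", {
  sim <- simulate_dataset(sim_config(seed = 28, n_peptidoforms = 40,
                                     ambiguity_rate = 0.5))
  merged <- merge_searches(sim$psm_runs)
  filtered <- filter_psms(merged)
  rec <- assignment_recovery(filtered, sim$truth$assignments, sim$psm_runs)
  expect_gte(rec$rate, 0.95)
})

test_that("fixtures round-trip through disk and the manifest hash tracks the config", {
  dir1 <- file.path(tempdir(), "sim_fix_a")
  sim <- simulate_dataset(sim_config(seed = 29, n_peptidoforms = 10))
  man1 <- write_fixtures(sim, dir1)
  xic_back <- read_tsv(file.path(dir1, "xic.tsv"))
  expect_equal(xic_back$LightArea, sim$xic$LightArea, tolerance = 1e-9)
  expect_equal(xic_back$Peptidoform, sim$xic$Peptidoform)
  design_back <- read_tsv(file.path(dir1, "design.tsv"))
  expect_equal(design_back$Sample, sim$design$Sample)
  # identical config -> identical hash; changed config -> changed hash
  man1b <- write_fixtures(sim, dir1)
  expect_equal(man1$config_hash, man1b$config_hash)
  sim2 <- simulate_dataset(sim_config(seed = 30, n_peptidoforms = 10))
  man2 <- write_fixtures(sim2, file.path(tempdir(), "sim_fix_b"))
  expect_false(man1$config_hash == man2$config_hash)
  # the on-disk fixtures drive the pipeline end to end
  psm_files <- list.files(dir1, pattern = "^psm_", full.names = TRUE)
  runs <- lapply(psm_files, read_tsv)
  res <- run_pipeline(runs, xic_back, design_back)
  expect_gt(nrow(res$filtered), 0)
})
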