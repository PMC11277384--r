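test_that("relative abundance divides by the group total and sums to 100", {
  expect_equal(relative_abundance(c(50, 50)), c(50, 50))
  expect_equal(relative_abundance(500), 100)
  expect_equal(relative_abundance(c(500, 300, 200)), c(50, 30, 20))
  set.seed(8)
  for (i in 1:20) {
    a <- runif(sample(2:8, 1), 0, 1e9)
    expect_equal(sum(relative_abundance(a)), 100, tolerance = 1e-9)
  }
  # all-zero group: non-quantifiable, no division
  expect_true(all(is.na(relative_abundance(c(0, 0)))))
  expect_error(relative_abundance(c(-1, 5)), ">= 0")
})

test_that("combinatorial summing credits multi-modified forms to each single mod", {
  ra <- sum_combinatorial(c(400, 300, 200, 100),
                          list(character(0), "me1", "ac", c("me1", "ac")))
  expect_equal(ra[["me1"]], 40)
  expect_equal(ra[["ac"]], 30)
  expect_equal(ra[["unmod"]], 40)
  # no combo forms: identical to plain %RA
  ra2 <- sum_combinatorial(c(500, 300, 200),
                           list(character(0), "me1", "ac"))
  expect_equal(unname(ra2[c("unmod", "me1", "ac")]), c(50, 30, 20))
  # all area in one combo form: both mods at 100
  ra3 <- sum_combinatorial(1000, list(c("me1", "ac")))
  expect_equal(unname(ra3[c("me1", "ac")]), c(100, 100))
  expect_true(all(ra3 <= 100))
})

test_that("L/H ratios divide %RA values and never produce infinities", {
  expect_equal(lh_ratio(40, 20), 2)
  expect_equal(lh_ratio(0, 30), 0)
  expect_true(is.na(lh_ratio(40, 0)))
  expect_true(is.na(lh_ratio(40, NA)))
})

test_that("L/H is invariant to per-sample global intensity rescaling", {
  set.seed(9)
  for (i in 1:10) {
    light <- runif(5, 1, 100)
    heavy <- runif(5, 1, 100)
    scale <- runif(1, 0.1, 10)
    r1 <- lh_ratio(relative_abundance(light), relative_abundance(heavy))
    r2 <- lh_ratio(relative_abundance(light * scale),
                   relative_abundance(heavy))
    expect_equal(r1, r2, tolerance = 1e-12)
  }
})

test_that("quantifiability needs >=2 replicates, a spike-in ID and a resolved peak", {
  expect_false(quantifiability_filter(1, TRUE, TRUE))
  expect_false(quantifiability_filter(3, FALSE, TRUE))
  expect_false(quantifiability_filter(2, TRUE, FALSE))
  expect_true(quantifiability_filter(2, TRUE, TRUE))
  expect_equal(quantifiability_filter(c(1, 3, 2), c(TRUE, FALSE, TRUE),
                                      c(TRUE, TRUE, TRUE)),
               c(FALSE, FALSE, TRUE))
})

test_that("log2 normalization centers rows on the chosen reference", {
  m <- rbind(a = c(2, 2, 2), b = c(1, 2, 4))
  colnames(m) <- c("s1", "s2", "s3")
  n <- normalize_log2(m)
  expect_equal(unname(n["a", ]), c(0, 0, 0))
  expect_equal(unname(n["b", ]), c(-1, 0, 1))
  expect_equal(unname(rowMeans(n)), c(0, 0), tolerance = 1e-9)
  # untreated reference: row {1,1, treated 8} -> {0,0,3}
  m2 <- rbind(x = c(1, 1, 8))
  colnames(m2) <- c("u1", "u2", "t1")
  n2 <- normalize_log2(m2, "untreated", untreated = c("u1", "u2"))
  expect_equal(unname(n2["x", ]), c(0, 0, 3))
  # idempotence with the all-samples reference (ratios of centered ratios)
  n3 <- normalize_log2(2^n, "all_samples")
  expect_equal(n3, n, tolerance = 1e-12)
  # rows with no reference value stay missing, with a warning
  m4 <- rbind(y = c(NA, NA, 4))
  colnames(m4) <- c("u1", "u2", "t1")
  expect_warning(n4 <- normalize_log2(m4, "untreated", untreated = c("u1", "u2")),
                 "no reference")
  expect_true(all(is.na(n4)))
})

test_that("Tukey fences with interpolated quartiles mask the spec'd outliers", {
  expect_equal(remove_outliers(c(1, 2, 3, 4, 100)), c(1, 2, 3, 4, NA))
  expect_equal(remove_outliers(c(1, 2, 3, 4)), c(1, 2, 3, 4))
  expect_equal(remove_outliers(c(-100, 2, 3, 4, 5)), c(NA, 2, 3, 4, 5))
  # fewer than 4 non-missing values: no-op
  expect_equal(remove_outliers(c(1, 2, 1000)), c(1, 2, 1000))
  # matrix version with comparison groups
  m <- rbind(a = c(1, 2, 3, 4, 100, 1, 2, 3, 4, 5))
  grp <- rep(c("g1", "g2"), each = 5)
  out <- remove_outliers_matrix(m, grp)
  expect_true(is.na(out[1, 5]))
  expect_equal(sum(is.na(out)), 1)
})

test_that("mean imputation fills cells and drops hopeless rows", {
  m <- rbind(a = c(1, NA, 3), b = c(2, 2, 2), c = c(NA, NA, NA))
  expect_warning(imp <- impute_missing(m), "fully missing")
  expect_equal(unname(imp$matrix["a", 2]), 2)
  expect_equal(nrow(imp$matrix), 2)
  expect_true(imp$imputed["a", 2])
  expect_false(any(imp$imputed["b", ]))
  # no missing: identity
  m2 <- rbind(a = c(1, 2, 3))
  imp2 <- impute_missing(m2)
  expect_equal(imp2$matrix, m2)
})

test_that("quantify_xic computes per-window per-sample %RA in both channels", {
  xic <- data.frame(
    Peptidoform = c("W1 unmod", "W1 K9pr", "W2 unmod"),
    Window = c("W1", "W1", "W2"), Sequence = c("KSTGGKAPR", "KSTGGKAPR", "KQLATKAAR"),
    Mods = c("unmod", "K9pr", "unmod"), Sample = "s1",
    LightArea = c(750, 250, 500), HeavyArea = c(400, 100, NA),
    ResolvedPeak = TRUE, stringsAsFactors = FALSE)
  q <- quantify_xic(xic)
  expect_equal(q$LightRA, c(75, 25, 100))
  expect_equal(q$HeavyRA[1:2], c(80, 20))
  expect_equal(q$LH[1:2], c(75 / 80, 25 / 20))
  expect_true(is.na(q$LH[3]))
  expect_error(quantify_xic(rbind(xic, xic[1, ])), "more than one")
})
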