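test_that("protocol application follows the lysine-blocking chemistry", {
  # endogenous K14ac keeps its acetyl; free K9 gains the D3-acetyl label
  pf <- apply_protocol(w_h3_917, c("14" = "ac"), protocol_spec("D3Ac-PIC"))
  expect_equal(unname(pf$labels["9"]), "chem_d3ac")
  expect_false("14" %in% names(pf$labels))
  expect_equal(unname(pf$labels["0"]), "pic")
  # all-free case under PRO-PIC: both lysines propionylated
  pf2 <- apply_protocol(w_h3_917, NULL, protocol_spec("PRO-PIC"))
  expect_equal(unname(pf2$labels[c("9", "14")]), c("chem_pr", "chem_pr"))
  # me1 is retained alongside the label under D5PRO-D5PRO
  pf3 <- apply_protocol(w_h3_917, c("9" = "me1"), protocol_spec("D5PRO-D5PRO"))
  expect_equal(unname(pf3$endogenous["9"]), "me1")
  expect_equal(unname(pf3$labels["9"]), "chem_d5pr")
  expect_equal(unname(pf3$labels["14"]), "chem_d5pr")
  expect_equal(unname(pf3$labels["0"]), "nterm_d5pr")
})

test_that("protocol application validates endogenous input", {
  expect_error(apply_protocol(w_h3_917, c("8" = "ac"), protocol_spec("PRO-PIC")),
               "outside window")
  expect_error(
    apply_protocol(w_h3_917, c("9" = "ac", "9" = "pr"), protocol_spec("PRO-PIC")),
    "more than one")
  expect_error(apply_protocol(w_h3_917, c("10" = "ac"), protocol_spec("PRO-PIC")),
               "lysine")
  expect_error(apply_protocol(w_h3_917, c("9" = "chem_pr"), protocol_spec("PRO-PIC")),
               "chemical label")
})

test_that("mass additions match the rule application example", {
  d3 <- protocol_spec("D3Ac-PIC")
  bare <- sum(vapply(strsplit("KSTGGKAPR", "")[[1]],
                     function(a) composition_mass(histoneacyl:::aa_compositions()[[a]]),
                     numeric(1))) + composition_mass(c(H = 2, O = 1))
  pf <- apply_protocol(w_h3_917, c("14" = "ac"), d3)
  expect_equal(peptidoform_mass(pf) - bare, 45.0294 + 42.0106 + 119.0371,
               tolerance = 2e-4)
})

test_that("peptidoform mass: AR + PIC and the heavy-channel offset", {
  w <- peptide_window("X", 1, 2, "AR")
  pf <- apply_protocol(w, NULL, protocol_spec("PRO-PIC"))
  expect_equal(round(peptidoform_mass(pf), 4), 364.1859)
  # heavy - light = 10.008269 per arginine
  for (w2 in list(w, w_h3_2740, w_h4_tail)) {
    l <- apply_protocol(w2, NULL, protocol_spec("D3Ac-PIC"), "light")
    h <- apply_protocol(w2, NULL, protocol_spec("D3Ac-PIC"), "heavy")
    n_r <- lengths(regmatches(w2$sequence, gregexpr("R", w2$sequence)))
    expect_equal(peptidoform_mass(h) - peptidoform_mass(l),
                 10.008269 * n_r, tolerance = 1e-5)
  }
})

test_that("full D5-propionylation vs propionylation differs by 2 x 5.0314", {
  d5 <- apply_protocol(w_h3_917, NULL, protocol_spec("D5PRO-PIC"))
  pr <- apply_protocol(w_h3_917, NULL, protocol_spec("PRO-PIC"))
  expect_equal(round(peptidoform_mass(d5) - peptidoform_mass(pr), 4), 10.0628)
})

test_that("mass additivity: modified minus bare equals the sum of deltas", {
  mods <- mod_table()
  set.seed(11)
  protos <- protocol_names()
  for (i in 1:10) {
    proto <- protocol_spec(sample(protos, 1))
    endo <- c("9" = sample(c("me1", "ac", "pr", "bu", "cr"), 1))
    pf <- apply_protocol(w_h3_917, endo, proto)
    bare <- sum(vapply(strsplit(w_h3_917$sequence, "")[[1]],
                       function(a) composition_mass(histoneacyl:::aa_compositions()[[a]]),
                       numeric(1))) + composition_mass(c(H = 2, O = 1))
    deltas <- sum(vapply(c(pf$endogenous, pf$labels),
                         function(nm) mods[[nm]]$mass, numeric(1)))
    expect_equal(peptidoform_mass(pf), bare + deltas, tolerance = 1e-9)
  }
})

test_that("protocol invariance: with no endogenous mods every protocol labels all K", {
  for (p in protocol_names()) {
    for (w in list(w_h3_917, w_h3_1826, w_h3_2740, w_h4_tail)) {
      pf <- apply_protocol(w, NULL, protocol_spec(p))
      n_k <- lengths(regmatches(w$sequence, gregexpr("K", w$sequence)))
      expect_equal(sum(names(pf$labels) != "0"), n_k,
                   label = paste(p, window_id <- w$protein))
      expect_equal(sum(names(pf$labels) == "0"), 1)
    }
  }
})

test_that("enumerate_forms builds the Cartesian product and honors the cap", {
  p <- protocol_spec("PRO-PIC")
  f2 <- enumerate_forms(w_h3_917, list("9" = c("free", "pr")), p)
  expect_length(f2, 2)
  f16 <- enumerate_forms(w_h3_917,
                         list("9" = c("free", "me1", "ac", "pr"),
                              "14" = c("free", "me1", "ac", "pr")), p)
  expect_length(f16, 16)
  expect_equal(anyDuplicated(vapply(f16, peptidoform_key, character(1))), 0)
  expect_error(
    enumerate_forms(w_h3_917,
                    list("9" = c("free", "me1", "ac", "pr"),
                         "14" = c("free", "me1", "ac", "pr")), p, cap = 10),
    "search space too large")
})
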