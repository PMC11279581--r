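test_that("size classes follow the ultra-short/short/large length ranges", {
  expect_equal(size_class(5), "USP")
  expect_equal(size_class(6), "SP")
  expect_equal(size_class(26), "LARGE")
  # total and consistent over 1..100
  for (L in 1:100) {
    expected <- if (L <= 5) "USP" else if (L <= 25) "SP" else "LARGE"
    expect_equal(size_class(L), expected)
    expect_equal(is_small(L), L <= 25)
  }
  expect_error(size_class(0), "positive")
})

test_that("sequence tokenization handles bracketed nonstandard residues", {
  expect_equal(tokenize_sequence("GLC"), c("G", "L", "C"))
  expect_equal(tokenize_sequence("C[Orn]C"), c("C", "[Orn]", "C"))
  expect_equal(residue_chain("x", "C[Orn]C")$length, 3L)
  expect_error(tokenize_sequence("AC1"), "position 3")
  expect_error(tokenize_sequence("A[Orn"), "unterminated")
  expect_error(tokenize_sequence(""), "at least one")
})

test_that("ring classification reproduces the ontology labels", {
  cys <- ring_qualifier(residues = c("C", "C"))
  expect_equal(classify_ring(intrachain_bond("DSB", "SSB", 3, 9,
                                             qualifier = cys), 12)$label, "CST")
  expect_equal(classify_ring(intrachain_bond(
    "DSB", "SSB", 1, 2, qualifier = ring_qualifier(alpha_carbon = TRUE)),
    2)$label, "DSL")
  expect_equal(classify_ring(intrachain_bond("AMD", "MMB", 1, 2,
                                             head_to_tail = TRUE), 2)$label, "DKP")
  expect_equal(classify_ring(intrachain_bond("AMD", "MMB", 1, 8,
                                             head_to_tail = TRUE), 8)$label, "NCB")
  expect_equal(classify_ring(intrachain_bond("AMD", "SMB", 2, 8), 8)$label, "LAC")
  expect_equal(classify_ring(intrachain_bond("EST", "SMB", 2, 8), 8)$label, "LCN")
  expect_equal(classify_ring(intrachain_bond("EST", "MMB", 1, 8), 8)$label, "LCN")
  # coarse fallback when qualifiers are missing
  coarse <- classify_ring(intrachain_bond("TIE", "SMB", 2, 3), 8)
  expect_equal(coarse$label, "GENERIC")
  expect_true(coarse$coarse)
  # combination absent from the ontology
  expect_error(classify_ring(intrachain_bond("DSB", "MMB", 1, 5), 8), "ontology")
})

test_that("qualifier refinement yields a full label for every ontology pair", {
  cases <- list(
    list("TIE", "SMB", ring_qualifier(saturation = "saturated"), "THZD"),
    list("TIE", "SMB", ring_qualifier(saturation = "one_double_bond"), "THZN"),
    list("TIE", "SMB", ring_qualifier(saturation = "two_double_bonds"), "THZ"),
    list("TIE", "SSB", ring_qualifier(ring_members = 5,
                                      saturation = "saturated"), "THZD"),
    list("TIE", "SSB", ring_qualifier(ring_members = 6,
                                      saturation = "two_double_bonds"), "TZ"),
    list("TIE", "SSB", ring_qualifier(aminovinyl = FALSE), "LAN"),
    list("TIE", "SSB", ring_qualifier(aminovinyl = FALSE, methylated = TRUE),
         "MeLAN"),
    list("TIE", "SSB", ring_qualifier(aminovinyl = TRUE), "AVC"),
    list("TIE", "SSB", ring_qualifier(aminovinyl = TRUE, methylated = TRUE),
         "MeAVC"),
    list("ETH", "SMB", ring_qualifier(saturation = "one_double_bond"), "OXZN"),
    list("ETH", "SMB", ring_qualifier(saturation = "two_double_bonds"), "OXZ"),
    list("ETH", "SMB", ring_qualifier(saturation = "one_double_bond",
                                      methylated = TRUE), "MeOXZN"),
    list("ETH", "SMB", ring_qualifier(saturation = "two_double_bonds",
                                      methylated = TRUE), "MeOXZ"),
    list("ETH", "SSB", NULL, "LAC"),
    list("AMN", "SMB", ring_qualifier(ring_members = 4), "BLAC"),
    list("AMN", "SMB", ring_qualifier(ring_members = 5), "PRL"),
    list("AMN", "SMB", ring_qualifier(ring_members = 6), "DLAC"),
    list("AMN", "SMB", ring_qualifier(ring_members = Inf), "LAC"),
    list("AMN", "SSB", NULL, "LAC"),
    list("IMN", "MMB", NULL, "LAC"),
    list("CAR", "SMB", NULL, "LAC"),
    list("CAR", "SSB", ring_qualifier(biaryl = TRUE), "BAR"),
    list("CAR", "SSB", ring_qualifier(biaryl = FALSE), "LAC"),
    list("CAR", "MMB", NULL, "PYR")
  )
  for (cs in cases) {
    b <- intrachain_bond(cs[[1]], cs[[2]], 2, 6, qualifier = cs[[3]])
    got <- classify_ring(b, 10)
    expect_equal(got$label, cs[[4]],
                 label = paste(cs[[1]], cs[[2]], "->", got$label))
    expect_false(got$coarse)
  }
})

test_that("record validation flags exactly the seeded violations", {
  good <- make_dsb_record("ok", 12, rbind(c(3, 9)))
  expect_length(validate_record(good), 0)

  # out-of-range bond
  bad1 <- good
  bad1$bonds[[1]]$pos2 <- 40L
  expect_match(validate_record(bad1), "out of range", all = FALSE)

  # disulfide with identical positions (constructor forbids; mutate directly)
  bad2 <- good
  bad2$bonds[[1]]$pos2 <- bad2$bonds[[1]]$pos1
  expect_match(validate_record(bad2), "distinct positions", all = FALSE)

  # head-to-tail flag not spanning the chain
  bad3 <- good
  bad3$bonds[[1]]$head_to_tail <- TRUE
  expect_match(validate_record(bad3), "head-to-tail", all = FALSE)

  # fuzzed corpus: each mutation plants exactly one violation kind
  set.seed(42)
  for (i in 1:25) {
    rec <- make_dsb_record(paste0("f", i), 15, rbind(c(4, 11)))
    choice <- sample(3, 1)
    rec$bonds[[1]][[c("pos2", "kind", "linkage")[choice]]] <-
      list(99L, "XXX", "ZZZ")[[choice]]
    msgs <- validate_record(rec)
    expect_gte(length(msgs), 1)
  }
})

test_that("invalid MIC blocks are reported without aborting", {
  rec <- make_dsb_record("m", 12, rbind(c(3, 9)))
  rec$mic <- data.frame(strain = "E", gram = "sideways", value = -1,
                        unit = "ug/mL")
  msgs <- validate_record(rec)
  expect_match(msgs, "gram", all = FALSE)
  expect_match(msgs, "positive", all = FALSE)
})
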