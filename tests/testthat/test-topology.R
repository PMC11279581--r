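test_that("lasso parameters match hand evaluation of the s and p formulas", {
  lp <- lasso_params(20, 13, 19)
  expect_equal(lp$s, 0.75)
  expect_equal(lp$p, 1 / 12)

  lp2 <- lasso_params(18, 2, 17)
  expect_equal(lp2$s, 4 / 18)
  expect_equal(lp2$p, 1)

  lp3 <- lasso_params(10, 1, 10)
  expect_equal(lp3$s, 2 / 10)
  expect_true(is.na(lp3$p))

  expect_error(lasso_params(10, 5, 5), "n1 < n2")
  expect_error(lasso_params(10, 3, 11), "n1 < n2")
})

test_that("single-disulfide classification applies the s/p rule with subtypes", {
  expect_equal(classify_single_dsb(25, 18, 24)$value, "C_LL")  # s=0.8, p=1/17
  expect_equal(classify_single_dsb(18, 2, 17)$value, "HL")     # s~0.222
  expect_equal(classify_single_dsb(20, 1, 8)$value, "N_LL")    # n1=1 clause
  expect_equal(classify_single_dsb(20, 10, 12)$value, "AMBIGUOUS")
  # balanced tails with s >= 0.5 land in the rule gap, never silently HL
  expect_equal(classify_single_dsb(20, 9, 12)$value, "AMBIGUOUS")  # s=0.9, p=1
  # tie L - n2 = n1 (reachable via the n1 = 1 clause) resolves to C_LL
  expect_equal(classify_single_dsb(5, 1, 4)$value, "C_LL")
  # overriding the thresholds moves the decision boundary
  expect_equal(classify_single_dsb(20, 10, 12, s_cutoff = 0.99)$value, "HL")
})

test_that("loop sizes include both cysteines", {
  expect_equal(loop_size(1, 7), 7L)    # spacing 5
  expect_equal(loop_size(3, 12), 10L)  # spacing 8
  expect_equal(loop_size(4, 5), 2L)    # adjacent
  expect_error(loop_size(5, 5), "n1 < n2")
})

test_that("matching enumeration is exhaustive, duplicate-free and ordered", {
  m1 <- enumerate_matchings(1)
  expect_length(m1, 1)
  expect_equal(m1[[1]], matrix(c(1L, 2L), ncol = 2))

  m2 <- enumerate_matchings(2)
  expect_length(m2, 3)
  keys <- vapply(m2, function(m) paste(t(m), collapse = "-"), character(1))
  expect_equal(keys, c("1-2-3-4", "1-3-2-4", "1-4-2-3"))

  expect_length(enumerate_matchings(3), 15)
  expect_error(enumerate_matchings(0), "1..6")
  expect_error(enumerate_matchings(7), "1..6")

  # closed-form count agrees with an independent factorial formula and with
  # the enumeration, for every k in the guard
  for (k in 1:5) {
    ms <- enumerate_matchings(k)
    expect_equal(length(ms), count_matchings(k))
    expect_equal(count_matchings(k), factorial(2 * k) / (2^k * factorial(k)))
    expect_equal(anyDuplicated(vapply(ms, function(m) paste(t(m), collapse = "-"),
                                      character(1))), 0L)
  }
})

test_that("crossing counts agree with the endpoint-containment oracle", {
  expect_equal(crossing_count(rbind(c(1, 4), c(2, 3))), 0L)
  expect_equal(crossing_count(rbind(c(1, 3), c(2, 4))), 1L)
  expect_equal(crossing_count(rbind(c(1, 4), c(2, 5), c(3, 6))), 3L)
  for (k in 1:5) {
    for (m in enumerate_matchings(k)) {
      expect_equal(crossing_count(m), oracle_crossings(m))
    }
  }
})

test_that("pairing classes: one ladder, one string, Catalan non-crossing", {
  expect_equal(classify_matching(rbind(c(1, 4), c(2, 3)))$value, "LD")
  expect_equal(classify_matching(rbind(c(1, 2), c(3, 4)))$value, "SR")
  expect_equal(classify_matching(rbind(c(1, 3), c(2, 4)))$value, "CR")
  expect_equal(classify_matching(rbind(c(1, 6), c(2, 3), c(4, 5)))$value, "MIXED")

  for (k in 1:5) {
    cls <- vapply(enumerate_matchings(k), function(m) classify_matching(m)$value,
                  character(1))
    if (k >= 2) {
      expect_equal(sum(cls == "LD"), 1L)
      expect_equal(sum(cls == "SR"), 1L)
    }
    noncrossing <- sum(cls != "CR")
    expect_equal(noncrossing, catalan(k))
    if (k >= 3) expect_equal(sum(cls == "MIXED"), catalan(k) - 2)
    # CR iff crossing_count > 0, against the independent oracle
    for (m in enumerate_matchings(k)) {
      expect_equal(classify_matching(m)$value == "CR", oracle_crossings(m) > 0)
    }
  }
})

test_that("record-level topology uses DSB endpoints in chain order", {
  rec1 <- make_dsb_record("one", 25, rbind(c(18, 24)))
  tc1 <- classify_peptide_topology(rec1)
  expect_equal(tc1$class, "C_LL")
  expect_equal(tc1$k, 1L)
  expect_equal(tc1$s, 0.8)
  expect_equal(tc1$loop_sizes, 7L)

  # nested intervals 6 < 8 < 13 < 15 -> ordinals {1-4, 2-3} -> ladder
  rec2 <- make_dsb_record("two", 18, rbind(c(6, 15), c(8, 13)))
  tc2 <- classify_peptide_topology(rec2)
  expect_equal(tc2$class, "LD")
  expect_equal(tc2$crossing_count, 0L)

  # free cysteines in the sequence do not perturb the matching
  toks <- rep("A", 18); toks[c(6, 8, 13, 15)] <- "C"; toks[c(2, 10)] <- "C"
  rec3 <- make_dsb_record("three", 18, rbind(c(6, 15), c(8, 13)),
                          seq_tokens = toks)
  expect_equal(classify_peptide_topology(rec3)$class, "LD")

  rec4 <- peptide_record("AAAAAA", synthesis = "ribosomal", id = "none")
  expect_equal(classify_peptide_topology(rec4)$class, "NOT_DISULFIDE_CYCLIC")

  rec5 <- make_dsb_record("conflict", 18, rbind(c(6, 15), c(6, 13)))
  expect_error(classify_peptide_topology(rec5), "conflict")

  # strict three-class mode folds MIXED into SR
  rec6 <- make_dsb_record("mixed", 25, rbind(c(1, 24), c(5, 9), c(14, 18)))
  expect_equal(classify_peptide_topology(rec6)$class, "MIXED")
  expect_equal(classify_peptide_topology(rec6, strict_three_class = TRUE)$class,
               "SR")
})
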