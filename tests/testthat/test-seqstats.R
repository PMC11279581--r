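test_that("spacing profiles count pairs at exact inter-residue spacings", {
  p1 <- disaap("CAAAAAC", "CC", 10)
  expect_equal(unname(p1$counts[["5"]]), 1L)
  expect_equal(sum(p1$counts), 1L)

  p2 <- disaap("CCC", "CC", 2)
  expect_equal(unname(p2$counts), c(2L, 1L, 0L))

  p3 <- disaap(c("ACADA", "AACAA"), "CC", 4)
  expect_equal(sum(p3$counts), 0L)

  # ordered distinct pair: only first-then-second occurrences count
  p4 <- disaap("CAG", c("C", "G"), 4)
  expect_equal(unname(p4$counts[["1"]]), 1L)
  expect_equal(sum(disaap("GAC", c("C", "G"), 4)$counts), 0L)

  expect_error(disaap(character(0), "CC"), "non-empty")
})

test_that("spacing counts conserve the brute-force pair total", {
  set.seed(11)
  for (rep in 1:10) {
    seqs <- vapply(1:5, function(i) {
      paste(sample(c("A", "C", "G", "K"), sample(3:12, 1), replace = TRUE),
            collapse = "")
    }, character(1))
    for (pair in list(c("C", "C"), c("C", "G"), c("A", "K"))) {
      maxs <- 15L  # exceeds every length, so all pairs qualify
      prof <- disaap(seqs, pair, maxs)
      expect_equal(sum(prof$counts),
                   oracle_pair_total(seqs, pair[1], pair[2], maxs))
    }
  }
})

test_that("shuffle null preserves composition and recovers planted signal", {
  # permutation-invariant input: z = 0 at the only occupied spacing
  ns0 <- disaap_null("CC", "CC", 3, method = "shuffle",
                     n_shuffles = 100, seed = 4)
  expect_equal(ns0$observed[1], 1)
  expect_equal(ns0$z[1], 0)
  expect_false(any(ns0$degenerate))

  # no planted signal: z stays within Monte-Carlo bounds
  set.seed(21)
  seqs <- vapply(1:200, function(i) {
    paste(sample(AA_ALPHABET, 20, replace = TRUE), collapse = "")
  }, character(1))
  ns <- disaap_null(seqs, "CC", 10, method = "shuffle",
                    n_shuffles = 300, seed = 22)
  expect_true(all(abs(ns$z) < 4, na.rm = TRUE))

  # planted signal: every sequence ends C + 5 spacer + C
  set.seed(23)
  planted <- vapply(1:500, function(i) {
    body <- sample(setdiff(AA_ALPHABET, "C"), 10, replace = TRUE)
    spacer <- sample(setdiff(AA_ALPHABET, "C"), 5, replace = TRUE)
    paste(c(body, "C", spacer, "C"), collapse = "")
  }, character(1))
  nsp <- disaap_null(planted, "CC", 10, method = "shuffle",
                     n_shuffles = 200, seed = 24)
  expect_gt(nsp$z[6], 3)           # spacing 5
  expect_true(nsp$significant[6])  # BH-adjusted at 0.05

  expect_error(disaap_null(seqs, "CC", 10, method = "shuffle",
                           n_shuffles = 100), "seed")
  expect_error(disaap_null(seqs, "CC", 10, method = "shuffle",
                           n_shuffles = 10, seed = 1), "100")
})

test_that("analytic expectation matches the shuffle mean within 3 SE", {
  seqs <- c("CKCACKAAC", "AACKWCAC", "CCKKAAC", "GWCACAKC")
  n_sh <- 2000
  for (pair in list(c("C", "C"), c("C", "K"))) {
    an <- disaap_null(seqs, pair, 6, method = "analytic")
    sh <- disaap_null(seqs, pair, 6, method = "shuffle",
                      n_shuffles = n_sh, seed = 31)
    se <- sh$expected_sd / sqrt(n_sh)
    tol <- pmax(3 * se, 1e-9)
    expect_true(all(abs(an$expected_mean - sh$expected_mean) <= tol))
    # analytic route reports obs/expected ratio instead of z
    expect_true(all(is.na(an$z)))
    expect_false(any(is.na(an$ratio[an$expected_mean > 0])))
  }
})

test_that("composition pools residues and bracket tokens sum to one", {
  expect_equal(unname(composition("GGG")$frequencies[["G"]]), 1.0)
  cp <- composition(c("GA", "AG"))
  expect_equal(unname(cp$frequencies[["G"]]), 0.5)
  expect_equal(unname(cp$frequencies[["A"]]), 0.5)
  cp2 <- composition("C[Orn]C")
  expect_equal(unname(cp2$frequencies[["C"]]), 2 / 3)
  expect_equal(unname(cp2$frequencies[[UNUSUAL_SYMBOL]]), 1 / 3)
  # normalization invariant on a random corpus
  set.seed(5)
  seqs <- vapply(1:30, function(i) {
    paste(sample(AA_ALPHABET, sample(5:20, 1), replace = TRUE), collapse = "")
  }, character(1))
  cp3 <- composition(seqs)
  expect_equal(sum(cp3$frequencies), 1, tolerance = 1e-9)
  expect_equal(sum(cp3$counts), cp3$total_residues)
})

test_that("enrichment is antisymmetric and floors absent symbols", {
  a <- composition(c("CCCCKKKKGGGG"))
  b <- composition(c("CKKKKKKGGGWWW"))
  e_ab <- enrichment(a, b)
  e_ba <- enrichment(b, a)
  expect_equal(e_ab$log2_ratio, -e_ba$log2_ratio)

  e_id <- enrichment(a, a)
  expect_true(all(e_id$log2_ratio == 0))

  # 4-fold enrichment is +2 on the log2 scale
  f_set <- c(C = 0.10, G = 0.90)
  f_bg <- c(C = 0.025, G = 0.975)
  e2 <- enrichment(f_set, f_bg)
  expect_equal(e2$log2_ratio[e2$symbol == "C"], 2)

  # symbol absent from the set: large negative, flagged
  expect_true(e_ab[e_ab$symbol == "W", "floored"])
  expect_lt(e_ab[e_ab$symbol == "W", "log2_ratio"], -3)

  # flooring disabled: absent background symbol is an error
  expect_error(enrichment(c(C = 0.5, G = 0.5), c(G = 1),
                          pseudo_fraction = NULL), "lacks")
})
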