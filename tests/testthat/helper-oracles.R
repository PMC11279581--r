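# Independent oracles used across test files. These deliberately re-derive
# quantities by different routes than the implementation under test.

# chord crossing by the "exactly one endpoint inside" characterization
# (the implementation uses the a1 < a2 < b1 < b2 ordering test instead)
oracle_crossings <- function(m) {
  m <- t(apply(matrix(as.integer(m), ncol = 2), 1L, sort))
  k <- nrow(m)
  if (k < 2L) return(0L)
  n <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      inside <- m[j, ] > m[i, 1L] & m[j, ] < m[i, 2L]
      if (sum(inside) == 1L) n <- n + 1L
    }
  }
  n
}

catalan <- function(k) choose(2 * k, k) / (k + 1)

# brute-force pair counting: loop over every position pair of every sequence
oracle_pair_total <- function(seqs, a, b, max_spacing) {
  total <- 0L
  for (s in seqs) {
    tk <- strsplit(s, "", fixed = TRUE)[[1L]]
    L <- length(tk)
    for (i in seq_len(L)) {
      for (j in seq_len(L)) {
        if (j > i && (j - i - 1L) <= max_spacing &&
            tk[i] == a && tk[j] == b) {
          total <- total + 1L
        }
      }
    }
  }
  total
}

make_dsb_record <- function(id, L, pairs, seq_tokens = NULL) {
  if (is.null(seq_tokens)) {
    seq_tokens <- rep("A", L)
    seq_tokens[as.vector(pairs)] <- "C"
  }
  bonds <- lapply(seq_len(nrow(pairs)), function(i) {
    intrachain_bond("DSB", "SSB", pairs[i, 1L], pairs[i, 2L],
                    qualifier = ring_qualifier(residues = c("C", "C")))
  })
  peptide_record(residue_chain(id, seq_tokens), synthesis = "ribosomal",
                 bonds = bonds)
}
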