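# Chain topology of disulfide-bonded peptides.
#
# One bond: lasso-like (LL, with C- or N-terminal loop) vs hairpin-like (HL),
# decided by the loop-fraction statistic s and the tail-length ratio p.
# Several bonds: the cysteine pairing scheme, read as a chord diagram over the
# cysteine ordinals, is ladder-like (fully nested), a string of rings
# (sequential disjoint), crossed rings (>= 1 chord crossing), or mixed
# (non-crossing but neither pure scheme).

#' Lasso parameters for a single disulfide bond
#'
#' For a chain of length `L` with bonded cysteines at positions `n1 < n2`,
#' computes `s = (L - n2 + n1 + 1) / L` (the fraction of the chain outside
#' the loop interior, large when the loop is small and terminal) and the
#' tail-length ratio `p = (L - n2) / (n1 - 1)` (C-tail over N-tail;
#' undefined when `n1 = 1`, i.e. the N-tail is empty).
#'
#' @param L Chain length.
#' @param n1,n2 Cysteine positions, `1 <= n1 < n2 <= L`.
#' @return List of class `lasso_params` with fields `L`, `n1`, `n2`, `s`,
#'   `p` (`NA` when undefined).
#' @examples
#' lasso_params(20, 13, 19)   # s = 0.75, p = 1/12
#' @export
lasso_params <- function(L, n1, n2) {
  L <- as.integer(L); n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (anyNA(c(L, n1, n2)) || n1 < 1L || n2 <= n1 || n2 > L) {
    stop("positions must satisfy 1 <= n1 < n2 <= L", call. = FALSE)
  }
  s <- (L - n2 + n1 + 1) / L
  p <- if (n1 > 1L) (L - n2) / (n1 - 1) else NA_real_
  structure(list(L = L, n1 = n1, n2 = n2, s = s, p = p), class = "lasso_params")
}

#' Classify a single-disulfide peptide as lasso-like or hairpin-like
#'
#' Applies the s/p rule: when `s < 0.5` the cysteines sit near both termini
#' and the chain is hairpin-like (`HL`). Otherwise the peptide is lasso-like
#' (`LL`) when the N-tail is absent (`n1 = 1`) or one tail dominates
#' (`p <= 0.3` or `p >= 3`); lasso-like calls are subtyped `C_LL` when the
#' loop sits at the C-terminus (`L - n2 < n1`) and `N_LL` when at the
#' N-terminus (`L - n2 > n1`), with the tie `L - n2 = n1` resolved to `C_LL`.
#' Chains with `s >= 0.5` but balanced tails (`0.3 < p < 3`) fall in a gap of
#' the rule and are labelled `AMBIGUOUS` rather than coerced.
#'
#' @inheritParams lasso_params
#' @param s_cutoff Hairpin threshold on `s` (default 0.5).
#' @param p_cutoffs Length-2 numeric: the lasso rule fires when
#'   `p <= p_cutoffs[1]` or `p >= p_cutoffs[2]` (defaults 0.3 and 3).
#' @return List of class `single_bond_call` with fields `value` (one of
#'   `"C_LL"`, `"N_LL"`, `"HL"`, `"AMBIGUOUS"`) and `params`.
#' @examples
#' classify_single_dsb(25, 18, 24)  # C-terminal lasso loop
#' classify_single_dsb(18, 2, 17)   # hairpin
#' @export
classify_single_dsb <- function(L, n1, n2, s_cutoff = 0.5,
                                p_cutoffs = c(0.3, 3)) {
  par <- lasso_params(L, n1, n2)
  value <-
    if (par$s < s_cutoff) {
      "HL"
    } else if (par$n1 == 1L ||
               (!is.na(par$p) && (par$p <= p_cutoffs[1L] || par$p >= p_cutoffs[2L]))) {
      if ((par$L - par$n2) > par$n1) "N_LL" else "C_LL"
    } else {
      "AMBIGUOUS"
    }
  structure(list(value = value, params = par), class = "single_bond_call")
}

#' @export
print.single_bond_call <- function(x, ...) {
  cat("<single_bond_call> ", x$value,
      sprintf(" (L=%d, n1=%d, n2=%d, s=%.3f, p=%s)\n",
              x$params$L, x$params$n1, x$params$n2, x$params$s,
              if (is.na(x$params$p)) "undef" else sprintf("%.3f", x$params$p)),
      sep = "")
  invisible(x)
}

#' Inclusive loop size of a cysteine pair
#'
#' The number of residues in the disulfide-closed loop, both cysteines
#' included: `n2 - n1 + 1`, i.e. spacing + 2 where spacing counts residues
#' strictly between the pair. Spacings of 5 and 8 residues thus close loops
#' of 7 and 10.
#'
#' @param n1,n2 Cysteine positions with `n1 < n2`.
#' @return Integer loop size.
#' @examples
#' loop_size(1, 7)   # spacing 5 -> loop of 7
#' @export
loop_size <- function(n1, n2) {
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (anyNA(c(n1, n2)) || n1 >= n2) stop("requires n1 < n2", call. = FALSE)
  n2 - n1 + 1L
}

#' Enumerate all perfect matchings of 2k cysteine ordinals
#'
#' Generates every way of pairing `2k` cysteines into `k` disulfide bonds.
#' Each matching is a `k x 2` integer matrix with rows `(a, b)`, `a < b`,
#' sorted by first element; the list is exhaustive, duplicate-free and in
#' deterministic lexicographic order.
#'
#' @param k Number of bonds, `1 <= k <= 6` (the count grows as the double
#'   factorial `(2k - 1)!!`; 10395 at `k = 6`).
#' @return List of matchings.
#' @examples
#' length(enumerate_matchings(3))  # 15
#' @export
enumerate_matchings <- function(k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 6L) {
    stop("k must be an integer in 1..6", call. = FALSE)
  }
  recurse <- function(free) {
    if (length(free) == 0L) return(list(matrix(integer(0), ncol = 2)))
    a <- free[1L]
    out <- list()
    for (b in free[-1L]) {
      rest <- setdiff(free, c(a, b))
      for (sub in recurse(rest)) {
        out[[length(out) + 1L]] <- rbind(c(a, b), sub)
      }
    }
    out
  }
  ms <- recurse(seq_len(2L * k))
  lapply(ms, function(m) {
    m <- matrix(as.integer(m), ncol = 2)
    m[order(m[, 1L]), , drop = FALSE]
  })
}

#' Count perfect matchings of 2k points
#'
#' Closed form `(2k)! / (2^k k!)`, the double factorial `(2k - 1)!!`; equals
#' `length(enumerate_matchings(k))` within the enumeration guard.
#'
#' @param k Number of bonds, `k >= 1`.
#' @return Numeric count.
#' @examples
#' count_matchings(4)  # 105
#' @export
count_matchings <- function(k) {
  k <- as.integer(k)
  if (any(is.na(k)) || any(k < 1L)) stop("k must be a positive integer", call. = FALSE)
  vapply(k, function(kk) prod(seq(1, 2 * kk - 1, by = 2)), numeric(1))
}

as_matching <- function(m) {
  if (is.list(m) && !is.matrix(m)) m <- do.call(rbind, m)
  m <- matrix(as.integer(m), ncol = 2)
  m <- t(apply(m, 1L, sort))
  m <- m[order(m[, 1L]), , drop = FALSE]
  k <- nrow(m)
  if (!setequal(as.vector(m), seq_len(2L * k))) {
    stop("pairs must partition the ordinals 1..2k", call. = FALSE)
  }
  m
}

#' Number of chord crossings in a matching
#'
#' Counts pairs of chords `(a1, b1)`, `(a2, b2)` with `a1 < a2 < b1 < b2`
#' when the `2k` cysteine ordinals are drawn on a line — the standard
#' chord-diagram crossing number.
#'
#' @param m A matching: `k x 2` matrix (or list of pairs) over ordinals
#'   `1..2k`.
#' @return Non-negative integer.
#' @examples
#' crossing_count(rbind(c(1, 3), c(2, 4)))  # 1
#' @export
crossing_count <- function(m) {
  m <- as_matching(m)
  k <- nrow(m)
  if (k < 2L) return(0L)
  n <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      a1 <- m[i, 1L]; b1 <- m[i, 2L]; a2 <- m[j, 1L]; b2 <- m[j, 2L]
      if ((a1 < a2 && a2 < b1 && b1 < b2) || (a2 < a1 && a1 < b2 && b2 < b1)) {
        n <- n + 1L
      }
    }
  }
  n
}

#' Classify a cysteine pairing scheme
#'
#' `LD` (ladder-like) iff the matching is the fully nested scheme pairing
#' ordinal `i` with `2k + 1 - i`; `SR` (string of rings) iff it is the
#' sequential scheme pairing `2i - 1` with `2i`; `CR` (crossed rings) iff at
#' least one chord crossing exists; `MIXED` otherwise (non-crossing but
#' neither pure scheme — such matchings exist for `k >= 3`, the non-crossing
#' matchings numbering the Catalan number `C_k`).
#'
#' @inheritParams crossing_count
#' @return List of class `pairing_class` with fields `value` (one of
#'   `"LD"`, `"SR"`, `"CR"`, `"MIXED"`), `crossing_count`, `k`.
#' @examples
#' classify_matching(rbind(c(1, 4), c(2, 3)))  # LD
#' classify_matching(rbind(c(1, 2), c(3, 4)))  # SR
#' @export
classify_matching <- function(m) {
  m <- as_matching(m)
  k <- nrow(m)
  cc <- crossing_count(m)
  ladder <- cbind(seq_len(k), 2L * k + 1L - seq_len(k))
  string <- cbind(2L * seq_len(k) - 1L, 2L * seq_len(k))
  value <-
    if (cc > 0L) "CR"
    else if (isTRUE(all.equal(m, as_matching(ladder), check.attributes = FALSE))) "LD"
    else if (isTRUE(all.equal(m, as_matching(string), check.attributes = FALSE))) "SR"
    else "MIXED"
  structure(list(value = value, crossing_count = cc, k = k),
            class = "pairing_class")
}

#' @export
print.pairing_class <- function(x, ...) {
  cat("<pairing_class> ", x$value, " (k = ", x$k, ", crossings = ",
      x$crossing_count, ")\n", sep = "")
  invisible(x)
}

#' Classify the disulfide topology of a peptide record
#'
#' Derives the cysteine ordinals from the endpoints of the record's disulfide
#' bonds sorted by chain position (so free or nonstandard cysteines in the
#' sequence do not perturb the matching), then applies
#' [classify_single_dsb()] for one bond or [classify_matching()] for several.
#'
#' @param record A [peptide_record()] with at least one `DSB` bond.
#' @param strict_three_class Logical; when `TRUE`, `MIXED` multi-bond calls
#'   are reported as `SR` (string of rings with nesting), collapsing to the
#'   three-class scheme.
#' @return List of class `topology_call` with fields `id`, `k`, `class`,
#'   `s`, `p` (single-bond only, else `NA`), `crossing_count`, `loop_sizes`,
#'   `matching` (`NULL` for single-bond).
#' @examples
#' rec <- peptide_record("GKLLCKAFCKAWKAVCGSILCG", synthesis = "ribosomal",
#'   bonds = list(intrachain_bond("DSB", "SSB", 5, 16),
#'                intrachain_bond("DSB", "SSB", 9, 21)), id = "p")
#' classify_peptide_topology(rec)
#' @export
classify_peptide_topology <- function(record, strict_three_class = FALSE) {
  stopifnot(inherits(record, "peptide_record"))
  dsb <- Filter(function(b) b$kind == "DSB", record$bonds)
  L <- record$chain$length
  if (length(dsb) == 0L) {
    return(structure(list(id = record$chain$id, k = 0L,
                          class = "NOT_DISULFIDE_CYCLIC",
                          s = NA_real_, p = NA_real_, crossing_count = NA_integer_,
                          loop_sizes = integer(0), matching = NULL),
                     class = "topology_call"))
  }
  pos <- unlist(lapply(dsb, function(b) c(b$pos1, b$pos2)))
  if (anyDuplicated(pos)) {
    stop("conflict: a position is shared by two disulfide bonds", call. = FALSE)
  }
  if (max(pos) > L) stop("bond position out of range", call. = FALSE)
  k <- length(dsb)
  loops <- sort(vapply(dsb, function(b) loop_size(b$pos1, b$pos2), integer(1)))
  if (k == 1L) {
    call1 <- classify_single_dsb(L, dsb[[1L]]$pos1, dsb[[1L]]$pos2)
    return(structure(list(id = record$chain$id, k = 1L, class = call1$value,
                          s = call1$params$s, p = call1$params$p,
                          crossing_count = 0L, loop_sizes = loops,
                          matching = NULL),
                     class = "topology_call"))
  }
  ord <- stats::setNames(seq_along(pos), sort(pos))  # ordinals along the chain
  m <- t(vapply(dsb, function(b) {
    c(ord[[as.character(b$pos1)]], ord[[as.character(b$pos2)]])
  }, integer(2)))
  pc <- classify_matching(m)
  cls <- pc$value
  if (strict_three_class && cls == "MIXED") cls <- "SR"
  structure(list(id = record$chain$id, k = k, class = cls,
                 s = NA_real_, p = NA_real_,
                 crossing_count = pc$crossing_count, loop_sizes = loops,
                 matching = as_matching(m)),
            class = "topology_call")
}

#' @export
print.topology_call <- function(x, ...) {
  cat("<topology_call> ", x$id, ": ", x$class, " (k = ", x$k, ")\n", sep = "")
  invisible(x)
}

#' Tabulate topology calls for a set of records
#'
#' @param records List of [peptide_record()]s.
#' @param strict_three_class Passed to [classify_peptide_topology()].
#' @return data.frame with columns `id`, `k`, `class`, `s`, `p`,
#'   `crossing_count`, `loop_sizes` (comma-separated).
#' @export
topology_table <- function(records, strict_three_class = FALSE) {
  rows <- lapply(records, function(r) {
    tc <- classify_peptide_topology(r, strict_three_class = strict_three_class)
    data.frame(id = tc$id, k = tc$k, class = tc$class,
               s = tc$s, p = tc$p, crossing_count = tc$crossing_count,
               loop_sizes = paste(tc$loop_sizes, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
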