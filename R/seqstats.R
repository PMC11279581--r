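# The distribution of i-spaced amino-acid pairs (DiSAAP) with shuffle and
# analytic null models, and amino-acid composition enrichment against a
# background. Spacing convention: i counts residues strictly between the two
# pair members, so i = 0 is an adjacent pair and a pair spaced by 5 closes an
# inclusive loop of 7.

as_token_list <- function(sequences) {
  if (is.list(sequences)) {
    lapply(sequences, function(s) {
      if (inherits(s, "residue_chain")) s$tokens else as.character(s)
    })
  } else {
    lapply(as.character(sequences), tokenize_sequence)
  }
}

normalize_symbol <- function(tokens) {
  ifelse(grepl("^\\[.+\\]$", tokens), UNUSUAL_SYMBOL, tokens)
}

count_spacings <- function(tokens, first, second, max_spacing) {
  L <- length(tokens)
  counts <- integer(max_spacing + 1L)
  if (L >= 2L) {
    for (i in 0:min(max_spacing, L - 2L)) {
      j <- seq_len(L - i - 1L)
      counts[i + 1L] <- sum(tokens[j] == first & tokens[j + i + 1L] == second)
    }
  }
  counts
}

#' Distribution of i-spaced amino-acid pairs (DiSAAP)
#'
#' For a residue pair (a, b), `counts[i]` is the number of positions `j`
#' across all sequences with `seq[j] = a` and `seq[j + i + 1] = b`, i.e.
#' occurrences of the pair with exactly `i` residues strictly between. For
#' identical symbols (e.g. the Cys-Cys pair) each unordered occurrence is
#' counted once.
#'
#' @param sequences Character vector of sequence strings, or a list of token
#'   vectors / [residue_chain()]s.
#' @param pair Length-2 character vector of residue symbols, or a 2-character
#'   string such as `"CC"`.
#' @param max_spacing Largest spacing to tabulate (default 10).
#' @return Object of class `spacing_profile`: list with `pair`, `counts`
#'   (named by spacing `0..max_spacing`), `frequencies` (counts normalized by
#'   their total, `NaN`-free: zero total gives zeros), `n_sequences`,
#'   `total_pairs`.
#' @examples
#' disaap("CAAAAAC", "CC")$counts
#' @export
disaap <- function(sequences, pair, max_spacing = 10L) {
  toks <- as_token_list(sequences)
  if (length(toks) == 0L) stop("sequence set must be non-empty", call. = FALSE)
  max_spacing <- as.integer(max_spacing)
  if (is.na(max_spacing) || max_spacing < 0L) {
    stop("max_spacing must be >= 0", call. = FALSE)
  }
  if (length(pair) == 1L && nchar(pair) == 2L) {
    pair <- strsplit(pair, "", fixed = TRUE)[[1L]]
  }
  if (length(pair) != 2L) stop("pair must name two residue symbols", call. = FALSE)
  counts <- integer(max_spacing + 1L)
  for (tk in toks) {
    tk <- normalize_symbol(tk)
    counts <- counts + count_spacings(tk, pair[1L], pair[2L], max_spacing)
  }
  total <- sum(counts)
  structure(list(pair = pair,
                 counts = stats::setNames(counts, 0:max_spacing),
                 frequencies = stats::setNames(
                   if (total > 0) counts / total else rep(0, length(counts)),
                   0:max_spacing),
                 n_sequences = length(toks), total_pairs = total),
            class = "spacing_profile")
}

#' @export
print.spacing_profile <- function(x, ...) {
  cat("<spacing_profile> pair ", paste(x$pair, collapse = "-"), ", ",
      x$n_sequences, " sequence(s), ", x$total_pairs, " pair(s)\n", sep = "")
  print(x$counts)
  invisible(x)
}

analytic_expectation <- function(toks, first, second, max_spacing) {
  exp_i <- numeric(max_spacing + 1L)
  for (tk in toks) {
    L <- length(tk)
    if (L < 2L) next
    m1 <- sum(tk == first)
    per_slot <- if (first == second) {
      m1 * (m1 - 1) / (L * (L - 1))
    } else {
      m1 * sum(tk == second) / (L * (L - 1))
    }
    i <- 0:max_spacing
    slots <- pmax(L - i - 1L, 0L)
    exp_i <- exp_i + slots * per_slot
  }
  exp_i
}

#' Null model for the DiSAAP statistic
#'
#' Two null models for the observed spacing profile. `method = "shuffle"`
#' (primary): each sequence is independently permuted (an exact anagram, so
#' per-sequence length and composition are preserved) `n_shuffles` times;
#' per-spacing mean and sd over shuffles give z-scores
#' `z = (obs - mean) / sd`, and an empirical two-sided p-value with add-one
#' smoothing is computed from the null counts. `method = "analytic"`: the
#' positional-exchangeability expectation — for one sequence of length `L`
#' the expected count at spacing `i` is `(L - i - 1) m1 m2 / (L (L - 1))`
#' for distinct symbols with multiplicities `m1`, `m2`, and
#' `(L - i - 1) m (m - 1) / (L (L - 1))` for an identical pair; no sd is
#' available, so the observed/expected ratio is reported instead of z.
#'
#' Benjamini-Hochberg adjusted p-values across the tested spacings are
#' attached for the shuffle method (`p_adjust`, significance at `alpha`).
#'
#' @inheritParams disaap
#' @param method `"shuffle"` or `"analytic"`.
#' @param n_shuffles Number of permutations (shuffle method; >= 100).
#' @param seed Integer seed; required for the shuffle method.
#' @param alpha Benjamini-Hochberg level for flagging spacings (default 0.05).
#' @return Object of class `null_summary`: list with `method`, `spacing`,
#'   `observed`, `expected_mean`, `expected_sd` (shuffle only), `z`,
#'   `ratio`, `p_empirical`, `p_adjust`, `significant`, `degenerate`,
#'   `n_shuffles`, `seed`.
#' @examples
#' ns <- disaap_null(c("CAAAAAC", "CAKWAAC"), "CC", max_spacing = 6,
#'                   method = "shuffle", n_shuffles = 200, seed = 1)
#' ns$z
#' @export
disaap_null <- function(sequences, pair, max_spacing = 10L,
                        method = c("shuffle", "analytic"),
                        n_shuffles = 1000L, seed = NULL, alpha = 0.05) {
  method <- match.arg(method)
  toks <- as_token_list(sequences)
  if (length(toks) == 0L) stop("sequence set must be non-empty", call. = FALSE)
  obs_prof <- disaap(toks, pair, max_spacing)
  pair <- obs_prof$pair
  obs <- as.numeric(obs_prof$counts)
  spacing <- 0:max_spacing
  toks_n <- lapply(toks, normalize_symbol)

  if (method == "analytic") {
    mu <- analytic_expectation(toks_n, pair[1L], pair[2L], max_spacing)
    ratio <- ifelse(mu > 0, obs / mu, NA_real_)
    return(structure(list(method = "analytic", spacing = spacing,
                          observed = obs, expected_mean = mu,
                          expected_sd = rep(NA_real_, length(mu)),
                          z = rep(NA_real_, length(mu)), ratio = ratio,
                          p_empirical = rep(NA_real_, length(mu)),
                          p_adjust = rep(NA_real_, length(mu)),
                          significant = rep(NA, length(mu)),
                          degenerate = rep(FALSE, length(mu)),
                          n_shuffles = 0L, seed = NA_integer_),
                     class = "null_summary"))
  }

  n_shuffles <- as.integer(n_shuffles)
  if (is.na(n_shuffles) || n_shuffles < 100L) {
    stop("shuffle null requires n_shuffles >= 100", call. = FALSE)
  }
  if (is.null(seed)) {
    stop("configuration error: shuffle null requires an explicit seed",
         call. = FALSE)
  }
  null_counts <- matrix(0L, nrow = n_shuffles, ncol = max_spacing + 1L)
  set.seed(as.integer(seed))
  for (b in seq_len(n_shuffles)) {
    cnt <- integer(max_spacing + 1L)
    for (tk in toks_n) {
      cnt <- cnt + count_spacings(sample(tk), pair[1L], pair[2L], max_spacing)
    }
    null_counts[b, ] <- cnt
  }
  mu <- colMeans(null_counts)
  sdv <- apply(null_counts, 2L, stats::sd)
  degenerate <- sdv == 0 & obs != mu
  z <- ifelse(sdv > 0, (obs - mu) / sdv, ifelse(obs == mu, 0, NA_real_))
  # two-sided empirical p with add-one smoothing
  p_emp <- vapply(seq_along(obs), function(j) {
    (1 + sum(abs(null_counts[, j] - mu[j]) >= abs(obs[j] - mu[j]))) /
      (n_shuffles + 1)
  }, numeric(1))
  p_adj <- stats::p.adjust(p_emp, method = "BH")
  structure(list(method = "shuffle", spacing = spacing, observed = obs,
                 expected_mean = mu, expected_sd = sdv, z = z,
                 ratio = ifelse(mu > 0, obs / mu, NA_real_),
                 p_empirical = p_emp, p_adjust = p_adj,
                 significant = p_adj <= alpha, degenerate = degenerate,
                 n_shuffles = n_shuffles, seed = as.integer(seed)),
            class = "null_summary")
}

#' @export
print.null_summary <- function(x, ...) {
  cat("<null_summary> method = ", x$method, "\n", sep = "")
  print(as.data.frame(x[c("spacing", "observed", "expected_mean", "z",
                          "ratio", "p_empirical", "p_adjust")]))
  invisible(x)
}

#' Pooled amino-acid composition
#'
#' Residue fractions pooled over all sequences; bracketed nonstandard tokens
#' are pooled under the reserved symbol `"X"`.
#'
#' @inheritParams disaap
#' @return Object of class `composition_profile`: list with `counts`
#'   (named integer vector), `frequencies` (fractions summing to 1),
#'   `n_sequences`, `total_residues`.
#' @examples
#' composition(c("GA", "AG"))$frequencies
#' @export
composition <- function(sequences) {
  toks <- as_token_list(sequences)
  if (length(toks) == 0L) stop("sequence set must be non-empty", call. = FALSE)
  all_tokens <- normalize_symbol(unlist(toks))
  tab <- table(all_tokens)
  counts <- stats::setNames(as.integer(tab), names(tab))
  structure(list(counts = counts, frequencies = counts / sum(counts),
                 n_sequences = length(toks), total_residues = sum(counts)),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat("<composition_profile> ", x$n_sequences, " sequence(s), ",
      x$total_residues, " residue(s)\n", sep = "")
  print(round(x$frequencies, 4))
  invisible(x)
}

#' Composition enrichment against a background
#'
#' Per-symbol `log2(f_set / f_background)`. Fractions of symbols absent from
#' one side are floored at `pseudo_fraction` (applied symmetrically, so
#' `enrichment(A, B)` is exactly `-enrichment(B, A)`); floored symbols are
#' flagged. The symbol universe is the union of the two profiles and the
#' standard alphabet.
#'
#' @param profile,background [composition()] profiles (or named fraction
#'   vectors).
#' @param pseudo_fraction Flooring fraction for zero cells (default 1e-4);
#'   set to `NULL` to disable flooring, in which case a symbol present in
#'   the set but absent from the background is an error.
#' @param background_id Identifier recorded for the background.
#' @return data.frame of class `enrichment_table` with columns `symbol`,
#'   `f_set`, `f_background`, `log2_ratio`, `floored`.
#' @examples
#' a <- composition("CCCCKKKKKKGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG")
#' b <- composition("CKKKKKKKGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG")
#' enrichment(a, b)
#' @export
enrichment <- function(profile, background, pseudo_fraction = 1e-4,
                       background_id = "background") {
  fr <- function(x) {
    if (inherits(x, "composition_profile")) x$frequencies else x
  }
  f_set <- fr(profile); f_bg <- fr(background)
  symbols <- sort(unique(c(names(f_set), names(f_bg), AA_ALPHABET)))
  g <- function(f, s) if (s %in% names(f)) unname(f[[s]]) else 0
  fs <- vapply(symbols, g, numeric(1), f = f_set)
  fb <- vapply(symbols, g, numeric(1), f = f_bg)
  if (is.null(pseudo_fraction)) {
    missing_bg <- symbols[fs > 0 & fb == 0]
    if (length(missing_bg) > 0L) {
      stop("background lacks symbol(s) present in the set with flooring ",
           "disabled: ", paste(missing_bg, collapse = ", "), call. = FALSE)
    }
    keep <- fs > 0 & fb > 0
    symbols <- symbols[keep]; fs <- fs[keep]; fb <- fb[keep]
    floored_set <- rep(FALSE, length(symbols))
    floored_bg <- rep(FALSE, length(symbols))
  } else {
    floored_set <- fs < pseudo_fraction
    floored_bg <- fb < pseudo_fraction
    fs <- pmax(fs, pseudo_fraction)
    fb <- pmax(fb, pseudo_fraction)
  }
  out <- data.frame(symbol = symbols, f_set = fs, f_background = fb,
                    log2_ratio = log2(fs / fb),
                    floored = floored_set | floored_bg,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "background_id") <- background_id
  class(out) <- c("enrichment_table", "data.frame")
  out
}
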