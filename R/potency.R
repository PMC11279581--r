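# The cyclization-impact statistic on paired linear/cyclic MICs.
#
# MICs come from a broth microdilution assay on a two-fold dilution series,
# so the natural scale is log2: r = log2(MICc / MICl) measures the shift in
# dilution steps caused by cyclizing the chain. The assay resolves two
# compounds reliably only when their MICs differ by two or more dilutions;
# smaller differences are within experimental error. Lower MIC means more
# potent, so negative r favours the cyclic form.

#' Signed log2 MIC ratio for a linear/cyclic peptide pair
#'
#' `r = log2(mic_c / mic_l)` in dilution units; `delta_mic` is `r` rounded to
#' the nearest integer dilution (half away from zero). The pair is `reliable`
#' only when `|delta_mic| >= 2` (the two-fold dilution assay cannot resolve a
#' one-dilution difference); unreliable pairs are directionally
#' `indistinguishable`, otherwise the direction is `cyclic_more_potent`
#' (`delta_mic < 0`) or `linear_more_potent` (`delta_mic > 0`).
#'
#' @param mic_c,mic_l Positive MICs of the cyclic and linear peptide, in
#'   identical units.
#' @param unit_c,unit_l Optional unit tags; when both given they must match.
#' @param reliability_cutoff Minimum `|delta_mic|`, in dilutions, for a
#'   reliable call (default 2).
#' @return List of class `delta_mic_result` with fields `r`, `delta_mic`,
#'   `reliable`, `direction`.
#' @examples
#' delta_mic(32, 8)   # +2 dilutions, reliably less potent when cyclized
#' delta_mic(4, 8)    # one dilution: within assay error
#' @export
delta_mic <- function(mic_c, mic_l, unit_c = NULL, unit_l = NULL,
                      reliability_cutoff = 2) {
  if (!is.null(unit_c) && !is.null(unit_l) && !identical(unit_c, unit_l)) {
    stop("MIC units differ within a pair: ", unit_c, " vs ", unit_l,
         call. = FALSE)
  }
  if (!is.numeric(mic_c) || !is.numeric(mic_l) ||
      !is.finite(mic_c) || !is.finite(mic_l) || mic_c <= 0 || mic_l <= 0) {
    stop("MIC values must be positive and finite", call. = FALSE)
  }
  # difference of logs, not log of ratio: keeps r(a,b) == -r(b,a) exact
  r <- log2(mic_c) - log2(mic_l)
  dm <- sign(r) * floor(abs(r) + 0.5)   # half away from zero
  reliable <- abs(dm) >= reliability_cutoff
  direction <- if (!reliable) "indistinguishable"
               else if (dm < 0) "cyclic_more_potent"
               else "linear_more_potent"
  structure(list(r = r, delta_mic = dm, reliable = reliable,
                 direction = direction),
            class = "delta_mic_result")
}

#' @export
print.delta_mic_result <- function(x, ...) {
  cat(sprintf("<delta_mic_result> r = %.3f, delta_mic = %+d (%s%s)\n",
              x$r, as.integer(x$delta_mic), x$direction,
              if (x$reliable) "" else ", within assay error"))
  invisible(x)
}

#' Apply delta_mic to a table of MIC pairs
#'
#' @param pairs data.frame with columns `mic_cyclic` and `mic_linear`
#'   (positive, identical units per pair); any other columns (`id`,
#'   `sequence`, `bond_set`, `strain`, `gram`, `unit`) are carried through.
#' @return data.frame: input columns plus `r`, `delta_mic`, `reliable`,
#'   `direction`.
#' @export
delta_mic_table <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("mic_cyclic", "mic_linear") %in% names(pairs)))
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    delta_mic(pairs$mic_cyclic[i], pairs$mic_linear[i])
  })
  pairs$r <- vapply(res, `[[`, numeric(1), "r")
  pairs$delta_mic <- vapply(res, `[[`, numeric(1), "delta_mic")
  pairs$reliable <- vapply(res, `[[`, logical(1), "reliable")
  pairs$direction <- vapply(res, `[[`, character(1), "direction")
  pairs
}

#' Summarize delta-MIC results by group
#'
#' @param results data.frame as returned by [delta_mic_table()].
#' @param group_keys Character subset of `c("bond_set", "gram", "strain")`;
#'   empty for a single overall row.
#' @return data.frame, one row per group in deterministic key order:
#'   `n`, `n_cyclic_more_potent`, `n_linear_more_potent`,
#'   `n_indistinguishable`, `median_delta_mic`, `frac_within_one_dilution`.
#' @export
summarize_pairs <- function(results, group_keys = character(0)) {
  stopifnot(is.data.frame(results), nrow(results) > 0L,
            all(c("delta_mic", "direction") %in% names(results)))
  allowed <- c("bond_set", "gram", "strain")
  if (!all(group_keys %in% allowed)) {
    stop("group_keys must be a subset of: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  }
  if (length(group_keys) == 0L) {
    groups <- list(all = results)
    key_tab <- NULL
  } else {
    key <- interaction(results[group_keys], drop = TRUE, sep = "\r")
    groups <- split(results, key)
    groups <- groups[order(names(groups))]
    key_mat <- do.call(rbind, strsplit(names(groups), "\r", fixed = TRUE))
    key_tab <- as.data.frame(key_mat, stringsAsFactors = FALSE)
    names(key_tab) <- group_keys
    row.names(key_tab) <- NULL
  }
  stats_tab <- do.call(rbind, lapply(groups, function(g) {
    data.frame(n = nrow(g),
               n_cyclic_more_potent = sum(g$direction == "cyclic_more_potent"),
               n_linear_more_potent = sum(g$direction == "linear_more_potent"),
               n_indistinguishable = sum(g$direction == "indistinguishable"),
               median_delta_mic = stats::median(g$delta_mic),
               frac_within_one_dilution = mean(abs(g$delta_mic) <= 1))
  }))
  row.names(stats_tab) <- NULL
  if (is.null(key_tab)) stats_tab else cbind(key_tab, stats_tab)
}
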