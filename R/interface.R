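# Readers/writers and the end-to-end report. Record collections travel as
# newline-delimited JSON (one object per peptide; bonds are nested, which a
# flat format cannot hold); flat TSV exports are provided for spreadsheets.
# FASTA is accepted for sequence-only statistics (bracketed tokens forbidden
# in FASTA mode).

#' Run configuration
#'
#' Bundles the analysis thresholds (defaulting to the standard rule values:
#' hairpin cutoff `s = 0.5`, lasso tail-ratio cutoffs 0.3 and 3, MIC
#' reliability cutoff of 2 dilutions) with the seed and reporting options.
#' Overridden thresholds are reported in the run manifest.
#'
#' @param seed Integer seed for any stochastic step (shuffle nulls).
#' @param s_cutoff,p_cutoffs,reliability_cutoff Classification thresholds;
#'   see [classify_single_dsb()] and [delta_mic()].
#' @param pair Residue pair for the spacing profile (default `"CC"`).
#' @param max_spacing Largest spacing tabulated (default 10).
#' @param n_shuffles Shuffle-null permutations (default 1000).
#' @param alpha Benjamini-Hochberg level (default 0.05).
#' @param strict Logical; abort on the first invalid input instead of
#'   collecting diagnostics.
#' @param strict_three_class Logical; collapse `MIXED` topology calls to `SR`.
#' @param out_dir Optional directory for TSV output.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, s_cutoff = 0.5, p_cutoffs = c(0.3, 3),
                       reliability_cutoff = 2, pair = "CC", max_spacing = 10L,
                       n_shuffles = 1000L, alpha = 0.05, strict = FALSE,
                       strict_three_class = FALSE, out_dir = NULL) {
  structure(list(seed = as.integer(seed), s_cutoff = s_cutoff,
                 p_cutoffs = p_cutoffs,
                 reliability_cutoff = reliability_cutoff, pair = pair,
                 max_spacing = as.integer(max_spacing),
                 n_shuffles = as.integer(n_shuffles), alpha = alpha,
                 strict = isTRUE(strict),
                 strict_three_class = isTRUE(strict_three_class),
                 out_dir = out_dir),
            class = "run_config")
}

record_to_list <- function(record) {
  bonds <- lapply(record$bonds, function(b) {
    out <- list(kind = b$kind, linkage = b$linkage,
                pos1 = b$pos1, pos2 = b$pos2, head_to_tail = b$head_to_tail)
    if (!is.null(b$qualifier)) {
      q <- b$qualifier
      qs <- Filter(function(v) !is.null(v) && !all(is.na(v)), unclass(q))
      if (length(qs) > 0L) out$qualifier <- qs
    }
    out
  })
  out <- list(id = record$chain$id,
              sequence = paste(record$chain$tokens, collapse = ""),
              synthesis = record$synthesis, bonds = bonds)
  if (!is.null(record$source_kingdom)) out$source_kingdom <- record$source_kingdom
  if (!is.null(record$target_object)) out$target_object <- record$target_object
  if (!is.null(record$mic)) out$mic <- record$mic
  out
}

list_to_record <- function(x) {
  bonds <- lapply(x$bonds, function(b) {
    q <- if (!is.null(b$qualifier)) do.call(ring_qualifier, b$qualifier) else NULL
    intrachain_bond(b$kind, b$linkage, b$pos1, b$pos2,
                    head_to_tail = isTRUE(b$head_to_tail), qualifier = q)
  })
  mic <- if (!is.null(x$mic)) as.data.frame(x$mic, stringsAsFactors = FALSE) else NULL
  rec <- peptide_record(residue_chain(x$id, x$sequence),
                        synthesis = x$synthesis, bonds = bonds,
                        source_kingdom = x$source_kingdom,
                        target_object = x$target_object, mic = mic)
  v <- validate_record(rec)
  if (length(v) > 0L) stop(paste(v, collapse = "; "), call. = FALSE)
  rec
}

#' Write peptide records as newline-delimited JSON
#'
#' @param records List of [peptide_record()]s or a `peptide_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  if (inherits(records, "peptide_set")) records <- records$records
  lines <- vapply(records, function(r) {
    as.character(jsonlite::toJSON(record_to_list(r), auto_unbox = TRUE,
                                  digits = NA, null = "null"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read peptide records from newline-delimited JSON
#'
#' One JSON object per line following the record schema (`id`, `sequence`,
#' `synthesis`, `bonds`, optional `source_kingdom`, `target_object`, `mic`).
#' In lenient mode (default) invalid lines are collected as diagnostics
#' attached to the result; in strict mode the first violation aborts.
#'
#' @param path Input file path.
#' @param strict Logical; abort on first invalid line.
#' @return List of [peptide_record()]s with attribute `"diagnostics"`
#'   (data.frame `line`, `message`).
#' @export
read_records <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) {
    warning("no records in '", path, "'", call. = FALSE)
    out <- list()
    attr(out, "diagnostics") <- data.frame(line = integer(0),
                                           message = character(0))
    return(out)
  }
  records <- list()
  diags <- list()
  for (i in which(keep)) {
    rec <- tryCatch({
      x <- jsonlite::fromJSON(lines[i], simplifyVector = TRUE,
                              simplifyDataFrame = TRUE)
      if (is.data.frame(x$bonds)) {
        x$bonds <- lapply(seq_len(nrow(x$bonds)), function(j) {
          b <- as.list(x$bonds[j, , drop = FALSE])
          if (!is.null(b$qualifier)) {
            q <- b$qualifier
            if (is.data.frame(q)) q <- as.list(q[1L, , drop = FALSE])
            q <- lapply(q, function(v) if (is.list(v)) unlist(v) else v)
            b$qualifier <- Filter(function(v) !all(is.na(v)), q)
            if (length(b$qualifier) == 0L) b$qualifier <- NULL
          }
          b
        })
      }
      list_to_record(x)
    }, error = function(e) {
      if (strict) {
        stop("line ", i, ": ", conditionMessage(e), call. = FALSE)
      }
      diags[[length(diags) + 1L]] <<- data.frame(
        line = i, message = conditionMessage(e), stringsAsFactors = FALSE)
      NULL
    })
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  attr(records, "diagnostics") <-
    if (length(diags) > 0L) do.call(rbind, diags)
    else data.frame(line = integer(0), message = character(0))
  records
}

#' Read residue chains from a FASTA file
#'
#' Standard FASTA with wrapped lines; ids are the first whitespace-delimited
#' token of each header; sequences are upper-cased and must use the standard
#' 20-letter alphabet (bracketed nonstandard tokens are not representable in
#' FASTA mode).
#'
#' @param path FASTA file path.
#' @return List of [residue_chain()]s.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("read_fasta requires the Biostrings package", call. = FALSE)
  }
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(aa))
  lapply(seq_along(seqs), function(i) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% AA_ALPHABET)
    if (length(bad) > 0L) {
      stop("record '", ids[i], "': non-alphabet character '",
           chars[bad[1L]], "' at position ", bad[1L], call. = FALSE)
    }
    residue_chain(ids[i], chars)
  })
}

#' Read a background composition table
#'
#' Two-column TSV (`symbol`, `fraction`); `#` lines are comments. Fractions
#' are renormalized to sum exactly to 1. An illustrative average-protein
#' background ships with the package:
#' `system.file("extdata", "example_background.tsv", package = "cyclopep")`.
#'
#' @param path TSV file path.
#' @return Named fraction vector usable as the `background` of
#'   [enrichment()] or [run_report()].
#' @export
read_background <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("symbol", "fraction") %in% names(tab))) {
    stop("background table needs columns 'symbol' and 'fraction'", call. = FALSE)
  }
  if (anyDuplicated(tab$symbol)) stop("duplicate background symbols", call. = FALSE)
  if (any(tab$fraction < 0) || sum(tab$fraction) <= 0) {
    stop("background fractions must be non-negative with positive sum",
         call. = FALSE)
  }
  stats::setNames(tab$fraction / sum(tab$fraction), tab$symbol)
}

ring_table <- function(records) {
  rows <- list()
  for (r in records) {
    for (j in seq_along(r$bonds)) {
      b <- r$bonds[[j]]
      rl <- tryCatch(classify_ring(b, r$chain$length),
                     error = function(e) ring_label("UNRESOLVED"))
      rows[[length(rows) + 1L]] <- data.frame(
        id = r$chain$id, bond = j, kind = b$kind, linkage = b$linkage,
        pos1 = b$pos1, pos2 = b$pos2, ring = rl$label, coarse = rl$coarse,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(id = character(0), bond = integer(0),
                      kind = character(0), linkage = character(0),
                      pos1 = integer(0), pos2 = integer(0),
                      ring = character(0), coarse = logical(0)))
  }
  do.call(rbind, rows)
}

#' Assemble the standard report for a record collection
#'
#' Runs every analysis the package offers on one set of records: size
#' classes, ring labels per bond, disulfide topology calls, the cysteine
#' spacing profile with its shuffle null, pooled composition (with
#' enrichment when a background is supplied), and the delta-MIC summary when
#' paired MIC data are supplied. Analyses whose inputs are missing are
#' skipped with a logged reason. Deterministic given the config seed.
#'
#' @param records List of [peptide_record()]s or a `peptide_set`.
#' @param config A [run_config()].
#' @param mic_pairs Optional data.frame of paired MICs (columns as in
#'   [generate_mic_pairs()]).
#' @param background Optional background composition for enrichment (a
#'   [composition()] profile or named fraction vector).
#' @return List of class `report_bundle`: data.frames `sizes`, `rings`,
#'   `topology`, `disaap`, `composition`, optional `enrichment` and
#'   `delta_mic`, plus `skipped` (named reasons) and `manifest`. When
#'   `config$out_dir` is set, each table is also written as TSV together
#'   with a `manifest.json`.
#' @export
run_report <- function(records, config = run_config(), mic_pairs = NULL,
                       background = NULL) {
  if (inherits(records, "peptide_set")) records <- records$records
  stopifnot(inherits(config, "run_config"), length(records) > 0L)
  skipped <- character(0)

  lens <- vapply(records, function(r) r$chain$length, integer(1))
  sizes <- data.frame(id = vapply(records, function(r) r$chain$id, character(1)),
                      length = lens, size_class = size_class(lens),
                      cyclic = vapply(records, function(r) length(r$bonds) > 0L,
                                      logical(1)),
                      stringsAsFactors = FALSE)

  rings <- ring_table(records)

  has_dsb <- vapply(records, function(r) {
    any(vapply(r$bonds, function(b) b$kind == "DSB", logical(1)))
  }, logical(1))
  topology <- if (any(has_dsb)) {
    topology_table(records[has_dsb],
                   strict_three_class = config$strict_three_class)
  } else {
    skipped["topology"] <- "no disulfide-bonded records"
    NULL
  }

  chains <- lapply(records, function(r) r$chain)
  prof <- disaap(chains, config$pair, config$max_spacing)
  nullsum <- disaap_null(chains, config$pair, config$max_spacing,
                         method = "shuffle", n_shuffles = config$n_shuffles,
                         seed = config$seed, alpha = config$alpha)
  disaap_tab <- data.frame(spacing = nullsum$spacing,
                           observed = nullsum$observed,
                           frequency = as.numeric(prof$frequencies),
                           expected_mean = nullsum$expected_mean,
                           expected_sd = nullsum$expected_sd,
                           z = nullsum$z, p_empirical = nullsum$p_empirical,
                           p_adjust = nullsum$p_adjust,
                           significant = nullsum$significant)

  comp <- composition(chains)
  comp_tab <- data.frame(symbol = names(comp$frequencies),
                         count = as.integer(comp$counts),
                         fraction = as.numeric(comp$frequencies),
                         stringsAsFactors = FALSE, row.names = NULL)
  enrich_tab <- if (!is.null(background)) {
    as.data.frame(enrichment(comp, background))
  } else {
    skipped["enrichment"] <- "no background composition supplied"
    NULL
  }

  dmic_tab <- if (!is.null(mic_pairs) && nrow(mic_pairs) > 0L) {
    res <- delta_mic_table(mic_pairs)
    keys <- intersect(c("bond_set", "gram"), names(mic_pairs))
    summarize_pairs(res, keys)
  } else {
    skipped["delta_mic"] <- "no paired MIC data supplied"
    NULL
  }

  digest <- {
    tmp <- tempfile(fileext = ".jsonl")
    on.exit(unlink(tmp), add = TRUE)
    write_records(records, tmp)
    unname(tools::md5sum(tmp))
  }
  manifest <- list(package = "cyclopep",
                   version = as.character(utils::packageVersion("cyclopep")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = config$seed,
                   thresholds = list(s_cutoff = config$s_cutoff,
                                     p_cutoffs = config$p_cutoffs,
                                     reliability_cutoff = config$reliability_cutoff),
                   pair = config$pair, max_spacing = config$max_spacing,
                   n_shuffles = config$n_shuffles, alpha = config$alpha,
                   n_records = length(records), records_md5 = digest,
                   skipped = as.list(skipped))

  bundle <- list(sizes = sizes, rings = rings, topology = topology,
                 disaap = disaap_tab, composition = comp_tab,
                 enrichment = enrich_tab, delta_mic = dmic_tab,
                 skipped = skipped, manifest = manifest)
  class(bundle) <- "report_bundle"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("sizes", "rings", "topology", "disaap", "composition",
                 "enrichment", "delta_mic")) {
      tab <- bundle[[nm]]
      if (!is.null(tab)) {
        utils::write.table(tab, file.path(config$out_dir, paste0(nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> ", x$manifest$n_records, " record(s); tables: ",
      paste(names(Filter(Negate(is.null),
                         x[c("sizes", "rings", "topology", "disaap",
                             "composition", "enrichment", "delta_mic")])),
            collapse = ", "), "\n", sep = "")
  if (length(x$skipped) > 0L) {
    cat("  skipped: ",
        paste(names(x$skipped), x$skipped, sep = " (", collapse = "), "),
        ")\n", sep = "")
  }
  invisible(x)
}
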