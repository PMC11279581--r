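# Domain types, validation, the ring ontology and size classes shared by all
# analysis stages. Positions are 1-based and inclusive throughout; residue
# tokens are one-letter codes plus bracketed multi-character tokens for
# nonstandard residues (e.g. "[Orn]"), which count toward length and are
# pooled under the reserved symbol "X" in composition work.

#' Standard amino-acid alphabet
#'
#' The twenty proteinogenic one-letter codes accepted as bare residue tokens.
#' Nonstandard residues must be written as bracketed tokens (`"[Orn]"`).
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Reserved symbol for nonstandard (bracketed) residues
#' @export
UNUSUAL_SYMBOL <- "X"

BOND_KINDS    <- c("AMD", "EST", "ETH", "TIE", "DSB", "AMN", "IMN", "CAR")
BOND_LINKAGES <- c("MMB", "SMB", "SSB")
SYNTH_ROUTES  <- c("ribosomal", "nonribosomal")
KINGDOMS      <- c("Animalia", "Plantae", "Protista", "Fungi", "Bacteria", "Archaea")
GRAM_CLASSES  <- c("positive", "negative")
SATURATIONS   <- c("saturated", "one_double_bond", "two_double_bonds")

RING_LABELS <- c("THZN", "THZD", "THZ", "TZ", "AVC", "MeAVC", "LAN", "MeLAN",
                 "OXZN", "MeOXZN", "OXZ", "MeOXZ", "LCN", "CST", "DSL", "NCB",
                 "LAC", "DKP", "BLAC", "DLAC", "PRL", "BAR", "PYR",
                 "GENERIC", "UNRESOLVED")

# (kind, linkage) pairs admitted by the ring ontology
ONTOLOGY_PAIRS <- rbind(
  data.frame(kind = "TIE", linkage = c("SMB", "SSB")),
  data.frame(kind = "ETH", linkage = c("SMB", "SSB")),
  data.frame(kind = "EST", linkage = c("SMB", "MMB")),
  data.frame(kind = "DSB", linkage = "SSB"),
  data.frame(kind = "AMD", linkage = c("MMB", "SMB")),
  data.frame(kind = "IMN", linkage = "MMB"),
  data.frame(kind = "AMN", linkage = c("SMB", "SSB")),
  data.frame(kind = "CAR", linkage = c("SMB", "SSB", "MMB"))
)

#' Tokenize a peptide sequence
#'
#' Splits a sequence string into residue tokens: bare one-letter codes from
#' [AA_ALPHABET] and bracketed tokens such as `"[Orn]"` for nonstandard
#' residues. Token positions are 1-based.
#'
#' @param sequence Character scalar.
#' @return Character vector of tokens.
#' @examples
#' tokenize_sequence("GLC[Orn]KC")
#' @export
tokenize_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  if (nchar(sequence) == 0L) {
    stop("sequence must contain at least one residue token", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  tokens <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) {
        stop("unterminated bracketed token starting at character ", i, call. = FALSE)
      }
      if (j == i + 1L) {
        stop("empty bracketed token at character ", i, call. = FALSE)
      }
      tokens <- c(tokens, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch %in% AA_ALPHABET) {
      tokens <- c(tokens, ch)
      i <- i + 1L
    } else {
      stop("invalid residue character '", ch, "' at position ", i, call. = FALSE)
    }
  }
  tokens
}

#' Residue chain
#'
#' An identified, tokenized peptide sequence. Length `L` is the token count;
#' bracketed nonstandard residues count as one token each.
#'
#' @param id Character identifier.
#' @param sequence Sequence string, or a pre-tokenized character vector.
#' @return Object of class `residue_chain` with fields `id`, `tokens`, `length`.
#' @examples
#' ch <- residue_chain("pep1", "GLFDIIKKIAESF")
#' ch$length
#' @export
residue_chain <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  tokens <- if (length(sequence) > 1L) as.character(sequence) else tokenize_sequence(sequence)
  ok <- tokens %in% AA_ALPHABET | grepl("^\\[.+\\]$", tokens)
  if (!all(ok)) {
    stop("invalid residue token(s): ", paste(tokens[!ok], collapse = ", "), call. = FALSE)
  }
  structure(list(id = id, tokens = tokens, length = length(tokens)),
            class = "residue_chain")
}

#' @export
print.residue_chain <- function(x, ...) {
  cat("<residue_chain> ", x$id, " (L = ", x$length, ")\n", sep = "")
  cat("  ", paste(x$tokens, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Ring qualifier
#'
#' Optional chemical detail used to refine a ring label beyond what the
#' (bond kind, linkage) pair determines. Any field may be left `NA`; missing
#' detail yields a coarse label rather than a guess.
#'
#' @param ring_members Atom count of a small ring (4, 5, 6), or a value > 6
#'   (or `Inf`) for an explicit macrocycle; `NA` when unknown.
#' @param saturation One of `"saturated"`, `"one_double_bond"`,
#'   `"two_double_bonds"`, or `NA`.
#' @param methylated Logical; `NA` is treated as unmethylated.
#' @param residues Length-2 character vector of residue tokens at the two bond
#'   positions, or `NULL`.
#' @param alpha_carbon Logical; marks a disulfide joining two alpha carbons.
#' @param aminovinyl Logical; marks an aminovinyl-cysteine thioether (vs
#'   lanthionine) for sidechain-sidechain thioethers.
#' @param biaryl Logical; marks a biaryl staple for sidechain carbon bonds.
#' @return Object of class `ring_qualifier`.
#' @export
ring_qualifier <- function(ring_members = NA_real_, saturation = NA_character_,
                           methylated = NA, residues = NULL,
                           alpha_carbon = NA, aminovinyl = NA, biaryl = NA) {
  if (!is.na(saturation) && !saturation %in% SATURATIONS) {
    stop("saturation must be one of: ", paste(SATURATIONS, collapse = ", "), call. = FALSE)
  }
  structure(list(ring_members = as.numeric(ring_members), saturation = saturation,
                 methylated = methylated, residues = residues,
                 alpha_carbon = alpha_carbon, aminovinyl = aminovinyl,
                 biaryl = biaryl),
            class = "ring_qualifier")
}

#' Intrachain ring-closing bond
#'
#' One covalent bond cyclizing a peptide chain, characterized by bond kind
#' (amide, ester, ether, thioether, disulfide, amine, imine, carbon), linkage
#' (which chains it joins) and 1-based residue positions.
#'
#' @param kind One of `"AMD"`, `"EST"`, `"ETH"`, `"TIE"`, `"DSB"`, `"AMN"`,
#'   `"IMN"`, `"CAR"`.
#' @param linkage One of `"MMB"` (mainchain-mainchain), `"SMB"`
#'   (sidechain-mainchain), `"SSB"` (sidechain-sidechain).
#' @param pos1,pos2 Residue positions with `pos1 <= pos2`; disulfides require
#'   `pos1 < pos2`.
#' @param head_to_tail Logical; head-to-tail bonds are encoded as `pos1 = 1`,
#'   `pos2 = L`, `head_to_tail = TRUE`.
#' @param qualifier Optional [ring_qualifier()].
#' @return Object of class `intrachain_bond`.
#' @examples
#' intrachain_bond("DSB", "SSB", 3, 9)
#' @export
intrachain_bond <- function(kind, linkage, pos1, pos2, head_to_tail = FALSE,
                            qualifier = NULL) {
  if (!kind %in% BOND_KINDS) {
    stop("unknown bond kind '", kind, "'", call. = FALSE)
  }
  if (!linkage %in% BOND_LINKAGES) {
    stop("unknown linkage '", linkage, "'", call. = FALSE)
  }
  pos1 <- as.integer(pos1); pos2 <- as.integer(pos2)
  if (is.na(pos1) || is.na(pos2) || pos1 < 1L || pos2 < pos1) {
    stop("bond positions must satisfy 1 <= pos1 <= pos2", call. = FALSE)
  }
  if (kind == "DSB" && pos1 == pos2) {
    stop("disulfide requires two distinct positions", call. = FALSE)
  }
  if (!is.null(qualifier) && !inherits(qualifier, "ring_qualifier")) {
    qualifier <- do.call(ring_qualifier, qualifier)
  }
  structure(list(kind = kind, linkage = linkage, pos1 = pos1, pos2 = pos2,
                 head_to_tail = isTRUE(head_to_tail), qualifier = qualifier),
            class = "intrachain_bond")
}

#' @export
print.intrachain_bond <- function(x, ...) {
  cat("<intrachain_bond> ", x$kind, "/", x$linkage, " ", x$pos1, "-", x$pos2,
      if (x$head_to_tail) " (head-to-tail)" else "", "\n", sep = "")
  invisible(x)
}

#' Peptide record
#'
#' One peptide: its chain, synthesis route, ring-closing intrachain bonds, and
#' optional source kingdom, target object and MIC measurements. A peptide is
#' cyclic iff it has at least one bond.
#'
#' @param chain A [residue_chain()], or a sequence string (an id is then
#'   required via `id`).
#' @param synthesis `"ribosomal"` or `"nonribosomal"`.
#' @param bonds List of [intrachain_bond()] objects (possibly empty).
#' @param id Identifier used when `chain` is given as a bare sequence string.
#' @param source_kingdom Optional kingdom of origin.
#' @param target_object Optional free-text target category.
#' @param mic Optional data.frame with columns `strain`, `gram`, `value`,
#'   `unit`.
#' @return Object of class `peptide_record`.
#' @examples
#' peptide_record("GLFDIICKISC", synthesis = "ribosomal",
#'                bonds = list(intrachain_bond("DSB", "SSB", 7, 11)),
#'                id = "pep1")
#' @export
peptide_record <- function(chain, synthesis = c("ribosomal", "nonribosomal"),
                           bonds = list(), id = NULL, source_kingdom = NULL,
                           target_object = NULL, mic = NULL) {
  if (!inherits(chain, "residue_chain")) {
    if (is.null(id)) stop("id required when chain is a bare sequence", call. = FALSE)
    chain <- residue_chain(id, chain)
  }
  synthesis <- match.arg(synthesis)
  bonds <- lapply(bonds, function(b) {
    if (!inherits(b, "intrachain_bond")) do.call(intrachain_bond, b) else b
  })
  structure(list(chain = chain, synthesis = synthesis, bonds = bonds,
                 source_kingdom = source_kingdom, target_object = target_object,
                 mic = mic),
            class = "peptide_record")
}

#' @export
print.peptide_record <- function(x, ...) {
  cat("<peptide_record> ", x$chain$id, " (L = ", x$chain$length, ", ",
      x$synthesis, ", ", length(x$bonds), " bond(s))\n", sep = "")
  invisible(x)
}

#' Peptide size class
#'
#' Peptides of length <= 5 are ultra-short (`USP`), lengths 6-25 are short
#' (`SP`), and longer chains are `LARGE`. "Small" peptides are USP or SP
#' (<= 25 residues).
#'
#' @param length Positive integer vector of chain lengths.
#' @return Character vector with values `"USP"`, `"SP"`, `"LARGE"`.
#' @examples
#' size_class(c(2, 5, 6, 25, 26))
#' @export
size_class <- function(length) {
  length <- as.integer(length)
  if (any(is.na(length)) || any(length < 1L)) {
    stop("length must be a positive integer", call. = FALSE)
  }
  ifelse(length <= 5L, "USP", ifelse(length <= 25L, "SP", "LARGE"))
}

#' @rdname size_class
#' @export
is_small <- function(length) size_class(length) != "LARGE"

ring_label <- function(label, coarse = FALSE) {
  stopifnot(label %in% RING_LABELS)
  if (label %in% c("GENERIC", "UNRESOLVED")) coarse <- TRUE
  structure(list(label = label, coarse = coarse), class = "ring_label")
}

#' @export
print.ring_label <- function(x, ...) {
  cat("<ring_label> ", x$label, if (x$coarse) " (coarse)" else "", "\n", sep = "")
  invisible(x)
}

qual_field <- function(bond, field) {
  q <- bond$qualifier
  if (is.null(q)) return(NA)
  v <- q[[field]]
  if (is.null(v)) NA else v
}

#' Classify the ring closed by an intrachain bond
#'
#' Maps a bond to the ring it closes under the controlled ontology of
#' ring-closing bonds: the (kind, linkage) pair determines a ring family and
#' optional qualifiers (saturation, small-ring atom count, methylation,
#' residue identities) refine it. When qualifiers are insufficient to pick a
#' single label, the coarse fallback `GENERIC` is returned with
#' `coarse = TRUE` rather than guessing the chemistry.
#'
#' Key mappings: mainchain-mainchain amides are head-to-tail macrolactams
#' (`NCB`; `DKP` for cyclic dipeptides); sidechain amides are macrolactams
#' (`LAC`); esters close lactones (`LCN`); disulfides close cystine rings
#' (`CST`) when both residues are cysteine, or `DSL` when the bond joins two
#' alpha carbons; thioethers and ethers close five/six-membered heterocycles
#' (thiazoline/thiazolidine/thiazole/thiazine, oxazol(in)e and their
#' methylated forms) or the macrocyclic lanthionine/aminovinyl-cysteine rings.
#'
#' @param bond An [intrachain_bond()].
#' @param chain_length Positive integer chain length.
#' @return A `ring_label` object with fields `label` and `coarse`.
#' @examples
#' classify_ring(intrachain_bond("DSB", "SSB", 3, 9,
#'   qualifier = ring_qualifier(residues = c("C", "C"))), 12)
#' classify_ring(intrachain_bond("AMD", "MMB", 1, 2, head_to_tail = TRUE), 2)
#' @export
classify_ring <- function(bond, chain_length) {
  stopifnot(inherits(bond, "intrachain_bond"))
  chain_length <- as.integer(chain_length)
  if (is.na(chain_length) || chain_length < 1L) {
    stop("chain_length must be a positive integer", call. = FALSE)
  }
  if (bond$pos2 > chain_length) {
    stop("bond position out of range for chain length ", chain_length, call. = FALSE)
  }
  kind <- bond$kind; linkage <- bond$linkage
  known <- any(ONTOLOGY_PAIRS$kind == kind & ONTOLOGY_PAIRS$linkage == linkage)
  if (!known) {
    stop("ontology error: no ring is defined for bond kind '", kind,
         "' with linkage '", linkage, "'", call. = FALSE)
  }

  sat  <- qual_field(bond, "saturation")
  nmem <- qual_field(bond, "ring_members")
  meth <- isTRUE(qual_field(bond, "methylated"))
  res  <- bond$qualifier$residues

  me <- function(lab) if (meth) paste0("Me", lab) else lab

  if (kind == "AMD" && linkage == "MMB") {
    return(ring_label(if (chain_length == 2L) "DKP" else "NCB"))
  }
  if (kind == "AMD" && linkage == "SMB") return(ring_label("LAC"))
  if (kind == "EST") return(ring_label("LCN"))
  if (kind == "DSB") {
    if (isTRUE(qual_field(bond, "alpha_carbon"))) return(ring_label("DSL"))
    if (!is.null(res) && length(res) == 2L && !anyNA(res)) {
      if (all(res == "C")) return(ring_label("CST"))
      return(ring_label("UNRESOLVED"))
    }
    return(ring_label("GENERIC"))
  }
  if (kind == "TIE" && linkage == "SMB") {
    # all sidechain-mainchain thioether rings in the ontology are five-membered
    if (!is.na(sat)) {
      return(ring_label(switch(sat,
        saturated        = "THZD",
        one_double_bond  = "THZN",
        two_double_bonds = "THZ")))
    }
    return(ring_label("GENERIC"))
  }
  if (kind == "TIE" && linkage == "SSB") {
    if (!is.na(nmem) && nmem == 5 && identical(sat, "saturated")) {
      return(ring_label("THZD"))
    }
    if (!is.na(nmem) && nmem == 6 && identical(sat, "two_double_bonds")) {
      return(ring_label("TZ"))
    }
    av <- qual_field(bond, "aminovinyl")
    if ((is.na(nmem) || nmem > 6) && !is.na(av)) {
      return(ring_label(me(if (isTRUE(av)) "AVC" else "LAN")))
    }
    return(ring_label("GENERIC"))
  }
  if (kind == "ETH" && linkage == "SMB") {
    if (identical(sat, "one_double_bond"))  return(ring_label(me("OXZN")))
    if (identical(sat, "two_double_bonds")) return(ring_label(me("OXZ")))
    return(ring_label("GENERIC"))
  }
  if (kind == "ETH" && linkage == "SSB") return(ring_label("LAC"))
  if (kind == "AMN" && linkage == "SSB") return(ring_label("LAC"))
  if (kind == "AMN" && linkage == "SMB") {
    if (!is.na(nmem)) {
      if (nmem == 4) return(ring_label("BLAC"))
      if (nmem == 5) return(ring_label("PRL"))
      if (nmem == 6) return(ring_label("DLAC"))
      if (nmem > 6)  return(ring_label("LAC"))
    }
    return(ring_label("GENERIC"))
  }
  if (kind == "IMN") return(ring_label("LAC"))
  if (kind == "CAR" && linkage == "MMB") return(ring_label("PYR"))
  if (kind == "CAR" && linkage == "SMB") return(ring_label("LAC"))
  if (kind == "CAR" && linkage == "SSB") {
    b <- qual_field(bond, "biaryl")
    if (!is.na(b)) return(ring_label(if (isTRUE(b)) "BAR" else "LAC"))
    return(ring_label("GENERIC"))
  }
  ring_label("GENERIC")  # unreachable given the pair table
}

#' Validate a peptide record
#'
#' Checks every type invariant (token alphabet, bond vocabularies, position
#' ranges, disulfide distinctness, head-to-tail encoding, MIC fields) and
#' returns one message per violation in a stable order. Validation never
#' aborts; a well-formed record yields `character(0)`.
#'
#' @param record A [peptide_record()].
#' @return Character vector of violation messages (empty when valid).
#' @export
validate_record <- function(record) {
  msgs <- character(0)
  add <- function(m) msgs <<- c(msgs, m)
  if (!inherits(record, "peptide_record")) {
    return("not a peptide_record")
  }
  ch <- record$chain
  L <- ch$length
  if (L < 1L) add("chain must contain at least one residue")
  bad <- !(ch$tokens %in% AA_ALPHABET | grepl("^\\[.+\\]$", ch$tokens))
  if (any(bad)) add(paste0("invalid residue token at position ",
                           paste(which(bad), collapse = ",")))
  if (!record$synthesis %in% SYNTH_ROUTES) add("unknown synthesis route")
  if (!is.null(record$source_kingdom) && !record$source_kingdom %in% KINGDOMS) {
    add(paste0("unknown source kingdom '", record$source_kingdom, "'"))
  }
  for (i in seq_along(record$bonds)) {
    b <- record$bonds[[i]]
    pre <- paste0("bond ", i, ": ")
    if (!b$kind %in% BOND_KINDS) add(paste0(pre, "unknown bond kind"))
    if (!b$linkage %in% BOND_LINKAGES) add(paste0(pre, "unknown linkage"))
    if (b$pos1 < 1L || b$pos2 > L) add(paste0(pre, "bond position out of range"))
    if (b$pos1 > b$pos2) add(paste0(pre, "positions out of order"))
    if (b$kind == "DSB" && b$pos1 == b$pos2) {
      add(paste0(pre, "disulfide requires two distinct positions"))
    }
    if (b$head_to_tail && !(b$pos1 == 1L && b$pos2 == L)) {
      add(paste0(pre, "head-to-tail bond must span positions 1..L"))
    }
    if (b$kind %in% BOND_KINDS && b$linkage %in% BOND_LINKAGES &&
        !any(ONTOLOGY_PAIRS$kind == b$kind & ONTOLOGY_PAIRS$linkage == b$linkage)) {
      add(paste0(pre, "no ring defined for (", b$kind, ", ", b$linkage, ")"))
    }
  }
  if (!is.null(record$mic)) {
    m <- record$mic
    need <- c("strain", "gram", "value", "unit")
    if (!is.data.frame(m) || !all(need %in% names(m))) {
      add("mic must be a data.frame with columns strain, gram, value, unit")
    } else {
      if (any(!m$gram %in% GRAM_CLASSES)) add("mic: gram must be positive/negative")
      if (any(!is.finite(m$value)) || any(m$value <= 0)) add("mic: values must be positive")
    }
  }
  msgs
}
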