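---
title: "Methods: topology, spacing and potency statistics for small cyclic peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topology, spacing and potency statistics for small cyclic peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclopep)
```

`cyclopep` analyses small cyclic peptides — chains of at most 25 residues
closed by one or more intrachain covalent bonds — as they appear in curated
antimicrobial-peptide databases: a sequence in one-letter code (with
bracketed tokens such as `[Orn]` for nonstandard residues), a synthesis
route (ribosomal or non-ribosomal), and annotated ring-closing bonds with
their kind, linkage and 1-based positions. This vignette documents the
models the package implements, the parameters that matter, the design
choices made where the underlying rules were open, and what the synthetic
generator does and does not emulate.

## Size classes and the record model

Chains of length ≤ 5 are ultra-short (`USP`), 6–25 short (`SP`), and
anything longer `LARGE`; "small" means ≤ 25 residues. Positions are 1-based
and inclusive everywhere. Bracketed nonstandard tokens count toward length
and are pooled under the reserved symbol `X` in composition work: the
package treats them as opaque, making no attempt to interpret their
chemistry. A record is cyclic iff it carries at least one bond;
`validate_record()` reports every invariant violation (never aborting), and
head-to-tail bonds are canonically encoded as `pos1 = 1`, `pos2 = L` with
the `head_to_tail` flag set.

## The ring ontology

Each ring is characterized by three coordinates: the bond kind (`AMD`,
`EST`, `ETH`, `TIE`, `DSB`, `AMN`, `IMN`, `CAR`), the linkage (`MMB`,
`SMB`, `SSB`), and the ring label. The (kind, linkage) pair fixes a ring
family; qualifiers refine it:

* saturation separates thiazolidine (`THZD`, saturated) from thiazoline
  (`THZN`, one double bond) and thiazole (`THZ`, two double bonds), and
  likewise oxazoline from oxazole;
* the small-ring atom count separates β-lactam (4), pyrrolidine (5) and
  δ-lactam (6) amine rings from macrolactams;
* a methylation flag produces the `Me`-variants; an `aminovinyl` flag
  separates aminovinyl-cysteine rings from lanthionines among
  sidechain–sidechain thioethers; a `biaryl` flag separates biaryl staples
  from macrolactams among sidechain carbon bonds;
* disulfides close cystine rings (`CST`) when both residues are cysteine
  and `DSL` when the qualifier marks an α-carbon linkage.

The classifier **never guesses chemistry**: when the qualifiers present
cannot single out one label (e.g. a thioether with unknown saturation), it
returns `GENERIC` with `coarse = TRUE`; when qualifiers are present but
incompatible with every label (a disulfide between two known non-cysteine,
non-α-carbon residues) it returns `UNRESOLVED`. A (kind, linkage) pair
outside the ontology is an error naming the pair. Three mappings deserve
note as deliberate choices. Mainchain–mainchain amides are always
head-to-tail macrolactams (`NCB`, or the diketopiperazine `DKP` for cyclic
dipeptides); the `head_to_tail` flag is validated against the positions
rather than consulted for the label, since no other mainchain amide ring
exists in the ontology. Mainchain-involving carbon bonds carry the pyridine
label `PYR` (the bond record holds a single linkage, and the
pyridine-forming carbon bridges involve the mainchain). Methylation absent
is treated as unmethylated rather than coarse, because the `Me`-variants
refine the same ring chemistry rather than naming a different ring. The
ontology keys on chemistry only; the synthesis route is carried separately
on the record and never influences a ring label.

## Single-disulfide topology: lasso-like vs hairpin-like

For one disulfide at cysteine positions `n1 < n2` on a chain of length `L`:

$$s = \frac{L - n_2 + n_1 + 1}{L}, \qquad p = \frac{L - n_2}{n_1 - 1}.$$

`s` is the fraction of the chain outside the loop interior (both cysteines
counted): a small terminal loop gives `s` near 1, cysteines near both
termini give `s` near `2/L`. `p` is the ratio of C-tail to N-tail length,
undefined when `n1 = 1` (no N-tail). The decision rule, with all thresholds
overridable through `run_config()` / function arguments:

* `s < 0.5` → hairpin-like (`HL`);
* otherwise, lasso-like (`LL`) when `n1 = 1` or `p ≤ 0.3` or `p ≥ 3`,
  subtyped `C_LL` when `L − n2 < n1` (loop at the C-terminus) and `N_LL`
  when `L − n2 > n1`;
* otherwise `AMBIGUOUS`.

Three points here were genuinely open and are resolved as package design
choices. First, the p-condition is sometimes written as a chained
inequality ("0.3 ≥ p ≥ 3") that no number satisfies; the geometric meaning
of a lasso — one tail much longer than the other — dictates the
disjunction `p ≤ 0.3 OR p ≥ 3`, which is what the package implements.
(Whether 0.3 was intended as 1/3, which would make the condition exactly
reciprocal-symmetric, cannot be settled; 0.3 is used as printed and is a
configurable threshold.) Second, the rule as stated leaves chains with
`s ≥ 0.5` but balanced tails (`0.3 < p < 3`) unassigned; the package
returns an explicit `AMBIGUOUS` label rather than silently coercing these
to `HL`, so downstream counts are never inflated by a hidden default.
Third, the subtype tie `L − n2 = n1` (reachable only through the `n1 = 1`
clause) is resolved to `C_LL`, consistent with the overwhelming prevalence
of C-terminal loops among natural single-disulfide peptides; this is a
documented tie-break, not part of the rule.

The loop closed by a cysteine pair has inclusive size `n2 − n1 + 1`
(spacing + 2): pairs spaced by 5 and 8 residues close loops of 7 and 10,
the sizes characteristic of Rana-box peptides and of the larger
single-loop families respectively.

## Multi-disulfide topology: chord-diagram pairing classes

With `k ≥ 2` disulfide bonds, the `2k` bonded cysteines are numbered
`1..2k` along the chain — ordinals are derived from the annotated bond
endpoints, not from scanning the sequence for `C`, so free or nonstandard
cysteines never perturb the matching (a position shared by two bonds is an
error). The pairing is then a perfect matching, i.e. a chord diagram:

* `LD` (ladder-like): the fully nested scheme `i ↔ 2k + 1 − i`;
* `SR` (string of rings): the sequential scheme `2i − 1 ↔ 2i`;
* `CR` (crossed rings): at least one chord crossing
  (`a1 < a2 < b1 < b2`);
* `MIXED`: non-crossing but neither pure scheme.

There are `(2k)!/(2^k k!)` matchings — the double factorial `(2k−1)!!` —
of which exactly one is `LD` and one is `SR` for every `k`, and the
non-crossing ones number the Catalan number `C_k`. Since `C_k > 2` for
`k ≥ 3`, non-crossing matchings exist that are neither ladder nor string
(e.g. `{1–6, 2–3, 4–5}`): a three-class scheme that sends every non-pure
matching to "crossed" would misdescribe them. The package therefore adds
the explicit fourth class `MIXED`; users who need strict three-class output
can set `strict_three_class = TRUE` (or the CLI flag
`--strict-three-class`), which folds `MIXED` into `SR` — a string of rings
with nesting — as the geometrically closest class. `enumerate_matchings()`
(guarded at `k ≤ 6`, where the count is 10395 and still instant) exists
precisely so that every classification claim can be checked exhaustively
rather than by spot cases; the test suite verifies the `CR ⇔ crossing`
equivalence against an independent endpoint-containment oracle for all
matchings up to `k = 5`.

## DiSAAP: the distribution of i-spaced residue pairs

For a residue pair `(a, b)`, `counts[i]` is the number of positions `j`
with `seq[j] = a` and `seq[j + i + 1] = b`, pooled over sequences: spacing
`i` counts residues strictly between the pair, so `i = 0` is adjacent and a
spacing-5 cysteine pair closes a 7-residue loop. Counting is ordered
(first symbol then second); for an identical pair such as Cys–Cys this
counts each unordered occurrence exactly once. Both raw counts and
normalized frequencies are reported, and pooling is over the whole corpus
(per-sequence profiles can be had by calling `disaap()` per sequence).

The null model is not prescribed by the underlying analysis tradition
beyond "random distribution", so the package provides two and documents
the choice:

* **shuffle** (primary): each sequence is independently permuted, so every
  null draw is an exact anagram — per-sequence length *and* composition
  are preserved, which is the conservative choice when composition itself
  is biased (cysteine-rich peptides). Per-spacing means and standard
  deviations over `n_shuffles` permutations give `z = (obs − mean)/sd`
  (`z = 0` when `sd = 0` and the observation equals the mean; flagged
  degenerate otherwise), and a two-sided empirical p-value with add-one
  smoothing, `(1 + #{|null − mean| ≥ |obs − mean|})/(n_shuffles + 1)`. A
  seed is mandatory — an unseeded shuffle request is a configuration
  error, because unreproducible nulls are worse than none. Across the
  tested spacings, Benjamini–Hochberg adjustment at a configurable level
  (default 0.05) flags significant spacings; the underlying analyses state
  no multiplicity procedure, so one had to be chosen, and BH across the 11
  default spacings is the standard mild correction.
* **analytic** (secondary): the positional-exchangeability expectation.
  For one sequence of length `L` containing `m1` and `m2` copies of two
  distinct symbols, each of the `L − i − 1` slots holds the ordered pair
  with probability `m1 m2 / (L(L−1))`, giving
  `E[counts_i] = (L − i − 1)\, m_1 m_2 / (L(L-1))`; for an identical pair
  the numerator is `m(m−1)`. (No doubling factor appears: the counting
  itself is ordered.) No closed-form sd is attempted; the
  observed/expected ratio is reported instead of `z`. The test suite
  checks the analytic mean against the shuffle mean within three standard
  errors at 2000 shuffles.

Composition profiles pool residue fractions (bracketed tokens under `X`),
and enrichment is the per-symbol `log2(f_set / f_background)` with both
fractions floored at a pseudo-fraction (default `1e-4`) so the table is
exactly antisymmetric under swapping set and background; floored symbols
are flagged, and flooring can be disabled, in which case a symbol missing
from the background is an error. The background must be supplied
explicitly; the shipped
`extdata/example_background.tsv` is an illustrative average-protein table
for demonstrations, not a measured reference.

## ΔMIC: the cyclization-impact statistic

For a linear/cyclic pair with identical sequence measured under identical
assay conditions, `r = log2(MIC_c / MIC_l)` in two-fold dilution units
(computed as a difference of logs so that antisymmetry
`r(a,b) = −r(b,a)` is exact in floating point). `delta_mic` is `r` rounded
to the nearest integer dilution, half away from zero, because the assay
reads out on a discrete two-fold series; raw `r` is always reported
alongside. A difference is **reliable** only when `|ΔMIC| ≥ 2` dilutions —
the broth microdilution assay cannot distinguish compounds one dilution
apart — and unreliable pairs are directionally `indistinguishable`. Lower
MIC means more potent, so `ΔMIC < 0` means cyclization improved potency;
this sign convention is stated explicitly because the formula is sometimes
printed with a `sgn(r)·r` decoration that collapses to `|r|` and cannot
express direction. `summarize_pairs()` aggregates by any subset of
bond-set (disulfide vs head-to-tail), gram class and strain, reporting
direction counts, the median `delta_mic` and the fraction within one
dilution.

## The synthetic generator

`generate_peptides()` emulates short ribosomal disulfide-bonded records
with planted, margin-safe structure; its defaults are the package's fixed
study conditions rather than tuning knobs:

* lengths 6–25 (the short-peptide range), drawn uniformly over the
  class-feasible subrange;
* class mix defaulting to C-terminal lassos as the most common
  single-bond class (0.35), then hairpins (0.25), ladders at two bonds
  (0.15), strings (0.08), crossed (0.07), mixed (0.05) and rare N-lassos
  (0.05) — echoing the qualitative inventory of natural short cyclic
  peptides (C-lassos vastly outnumber N-lassos; ladders dominate at two
  bonds, crossings at three or more);
* lasso loops of 7–8 residues (the observed loop sizes), hairpin
  cysteines within one residue of each terminus, multi-bond placements
  with consecutive-cysteine gaps ≥ 3 so that no bonded pair has spacing
  < 2 — adjacent or 1-spaced cysteine pairs cannot form a disulfide for
  steric reasons, and the generator refuses to plant them by default;
* margins: class minimum lengths (15 for `C_LL`, 14 for `N_LL`, 12 for
  `HL`; 10/16/22 for k = 2/3/4) keep every placement strictly away from
  the `s`/`p` decision thresholds, so recovery is exact by construction,
  and an infeasible class/length combination raises a configuration error
  naming the constraint;
* non-cysteine positions draw from a uniform 20-letter background by
  default (`cys_gly_background()` provides a Cys/Gly-enriched preset
  mirroring the qualitative composition of natural disulfide-bonded short
  peptides without claiming measured values);
* optional spacing enrichment plants one extra Cys pair at a target
  spacing per sequence with probability `(fold − 1)` times the
  background-expected per-sequence pair count, so the observed count sits
  near `fold` times expectation;
* truth labels travel in a sidecar data.frame (`$truth`) that no analysis
  stage reads.

`generate_mic_pairs()` draws linear MICs uniformly from a two-fold grid
(default `2^-2 … 2^8` µg/mL), shifts by the planted effect in dilutions,
adds ±1-dilution noise with probability 0.25 per side by default (the
assay's stated single-dilution error), clamps off-grid values to the grid
ends with a flag, and tags half the pairs as disulfide-cyclized, half
head-to-tail, with alternating gram class — mirroring the paired
comparison-set design used to assess cyclization impact.

What the generator does **not** emulate: nonstandard-residue chemistry
(bracket tokens are placeholders only), non-ribosomal scaffolds, realistic
per-family sequence signal (beyond composition), length–class correlations
in real databases, thioether/lanthionine ring systems, and measured MIC
distributions. Passing closed-loop tests therefore demonstrates that the
classifiers implement their definitions correctly and recover planted
structure under realistic sizes and noise — not that they reproduce any
particular database snapshot, whose counts depend on the database version.

## Numerical and implementation choices

* Thresholds (`s` cutoff 0.5, `p` cutoffs 0.3/3, reliability cutoff 2
  dilutions) default to the standard rule values and are overridable;
  overrides are recorded in the report manifest.
* `r` uses `log2(a) − log2(b)`; rounding is half-away-from-zero.
* Enrichment flooring is applied symmetrically to both sides, making
  antisymmetry exact.
* Matching enumeration recurses on the smallest unmatched ordinal, giving
  lexicographic order and duplicate-freeness by construction; the `k ≤ 6`
  guard bounds the count at 10395.
* Shuffle nulls use R's default RNG under an explicit seed;
  `run_report()` is byte-deterministic given the seed and inputs, and its
  manifest (package version, seed, thresholds, input digest) suffices to
  reproduce any table.
* Degenerate shuffle cells (`sd = 0`) yield `z = 0` when the observation
  equals the null mean and a flagged `NA` otherwise.

Problem sizes used by the test suite and the acceptance script — 1000
records for topology recovery, 500 for spacing enrichment with 200
shuffles, 200 MIC pairs, exhaustive matchings to `k = 5` — were chosen as
the smallest sizes at which the planted signals are unambiguous.

## Known limitations

* The ontology holds one linkage per bond; rings genuinely involving both
  mainchain and sidechain atoms on one side (pyridine bridges) are
  approximated by a single linkage choice.
* `AMBIGUOUS` single-bond calls are a real gap of the s/p rule, not an
  implementation artifact; users wanting a binary call must decide how to
  fold them.
* The analytic DiSAAP null has no variance, hence no significance; use the
  shuffle null for inference.
* FASTA input cannot carry bracketed nonstandard residues; use the JSON
  record format for those.
* No disulfide connectivity prediction: bonds must be annotated. No
  3-D structure, no SMILES/InChI parsing, no database API client.
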