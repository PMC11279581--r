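# cyclopep

Topology, ring ontology and potency statistics for small cyclic
antimicrobial peptides (AMPs).

Natural cyclic peptides of up to 25 residues — brevinin-type "Rana box"
amphibian peptides, protegrin-like hairpins, defensins, lantibiotics,
non-ribosomal depsipeptides — close their chains with a small repertoire of
intrachain bonds (amide, ester, ether, thioether, disulfide, amine, imine,
carbon). `cyclopep` provides the computational machinery to analyse such
peptides from annotated records:

* **Ring ontology** — every ring-closing bond is characterized by its bond
  kind, its linkage (mainchain–mainchain, sidechain–mainchain,
  sidechain–sidechain) and the ring it closes (`NCB`, `DKP`, `LAC`, `LCN`,
  `CST`, thiazole/oxazole heterocycles, lanthionines, …), with a coarse
  fallback when chemical qualifiers are missing.
* **Disulfide chain topology** — for one disulfide bond at cysteine
  positions `n1 < n2` on a chain of length `L`, the statistics

  ```
  s = (L − n2 + n1 + 1) / L        p = (L − n2) / (n1 − 1)
  ```

  classify the chain as hairpin-like (`HL`, `s < 0.5`) or lasso-like
  (`C_LL`/`N_LL`: `s ≥ 0.5` and one tail dominating, `p ≤ 0.3` or `p ≥ 3`
  or `n1 = 1`). For `k ≥ 2` bonds the cysteine pairing scheme, read as a
  chord diagram over the cysteine ordinals, is **ladder-like** (`LD`, fully
  nested), a **string of rings** (`SR`, sequential), **crossed rings**
  (`CR`, ≥ 1 chord crossing) or `MIXED` (non-crossing, neither pure
  scheme). All `(2k)!/(2^k k!)` pairings can be enumerated exhaustively;
  the non-crossing ones number the Catalan number `C_k`.
* **DiSAAP** — the distribution of *i*-spaced amino-acid pairs: counts of a
  residue pair (typically Cys–Cys) with exactly *i* residues between them,
  tested against a composition-preserving within-sequence shuffle null
  (z-scores, empirical p-values, Benjamini–Hochberg correction) and an
  analytic positional-exchangeability expectation.
* **Composition enrichment** — pooled residue fractions and
  `log2(f_set / f_background)` against a user-supplied background.
* **ΔMIC** — for linear/cyclic peptide pairs with identical sequences,
  `r = log2(MIC_cyclic / MIC_linear)` in two-fold dilution units; a
  difference is reliable only at two or more dilutions, smaller shifts
  being within broth-microdilution assay error.
* **Synthetic generator** — seeded database-like records with planted
  topology classes, spacing enrichment and cyclization effects, so the
  whole pipeline is testable closed-loop without external data.

## Worked example

```r
library(cyclopep)

rec <- peptide_record("GLFDIVKKVVGALGSLCKISKEC", synthesis = "ribosomal",
                      bonds = list(intrachain_bond("DSB", "SSB", 17, 23,
                        qualifier = ring_qualifier(residues = c("C", "C")))),
                      id = "brevinin_like")
classify_peptide_topology(rec)
#> <topology_call> brevinin_like: C_LL (k = 1)
```

The 23-mer with cysteines at 17 and 23 is called a C-terminal lasso
(`s = 0.783 ≥ 0.5`, `p = 0 ≤ 0.3`): a 7-residue disulfide loop
(`loop_size(17, 23) = 7`, the Rana-box motif) with a long N-terminal tail.
The bond itself closes a cystine macrolactam:

```r
classify_ring(rec$bonds[[1]], rec$chain$length)
#> <ring_label> CST
```

A synthetic corpus round-trips its planted classes and shows the
characteristic cysteine spacing signal:

```r
ps <- generate_peptides(synth_config(n_peptides = 200, seed = 42))
table(topology_table(ps$records)$class)
#>  C_LL    CR    HL    LD MIXED  N_LL    SR
#>    75    13    47    25     8    10    22

chains <- lapply(ps$records, function(r) r$chain)
ns <- disaap_null(chains, "CC", 10, method = "shuffle",
                  n_shuffles = 200, seed = 42)
round(ns$z, 1)
#> [1] -11.9 -12.2  11.0  -3.3  -6.5  14.0   3.2  -4.2   3.9  -0.8  -2.6
```

Spacings 0 and 1 are strongly depleted (z ≈ −12: adjacent cysteines cannot
form a disulfide for steric reasons and the generator respects that), while
spacing 5 — the 7-residue Rana-box loop — is strongly enriched (z = 14).

ΔMIC on 38 simulated linear/cyclic pairs with a planted −2-dilution effect
and one-dilution noise:

```r
mp <- generate_mic_pairs(synth_config(n_pairs = 38, effect_dilutions = -2,
                                      noise_prob = 0.25, seed = 42))
summarize_pairs(delta_mic_table(mp), "bond_set")
#>   bond_set  n n_cyclic_more_potent n_linear_more_potent n_indistinguishable
#> 1      DSB 19                    8                    0                  11
#> 2       HT 19                   14                    0                   5
#>   median_delta_mic frac_within_one_dilution
#> 1               -1                0.5789474
#> 2               -2                0.2631579
```

Negative medians mean the cyclic form is more potent (lower MIC); only
shifts of two or more dilutions count as reliable.

A thin command-line front end over these functions ships at
`system.file("scripts", "cyclopep.R", package = "cyclopep")` with
subcommands `classify | disaap | composition | delta-mic | simulate |
report`.

## Documentation

The methods vignette (`vignettes/cyclic-peptide-analysis.Rmd`) describes the
models, thresholds, null models, generator design and known limitations.
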