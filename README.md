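# dualfold

Detection of dual-fold coevolutionary signatures in protein families.

Fold-switching (metamorphic) proteins adopt two distinct stable
structures from one amino acid sequence, yet MSA-based structure
predictors almost always return a single conformation: deep superfamily
alignments are dominated by single-fold relatives whose coevolutionary
signal masks the couplings of the alternative fold. `dualfold`
implements **alternative contact enhancement (ACE)** for researchers in
structural bioinformatics who want to ask whether a family carries
evidence for a second fold:

1. prune a superfamily MSA into nested subfamily MSAs by sequence
   identity to the query (QID 1–50%, step 1%, duplicates collapsed;
   rows with >25% gaps then columns with >75% gaps removed);
2. run coupling inference on every MSA — a built-in MI/APC stand-in
   scorer, plus importers for externally computed couplings (pair lists
   or L×L matrices) — and z-score each run;
3. superpose all runs on one contact map, averaging each pair's z-score
   over the runs that scored it, and retain the top ⌊15L/2⌋ pairs;
4. denoise with DBSCAN (min cluster size 3), the radius chosen on an
   integer grid by an ROC rule (largest ε whose marginal ΔTP/ΔFP slope
   exceeds 1 while the next step's falls below 1, floored so no fewer
   contacts return than the deep-MSA-only baseline);
5. categorize filtered predictions against the dual-fold experimental
   contact map (heavy atoms, 8 Å intrachain / 10 Å interchain, ±2
   residue tolerance) as **common > dominant > alternative >
   unobserved**;
6. quantify enrichment with a one-tailed hypergeometric test
   (log-gamma evaluation; noise universe L² − N<sub>exp</sub>),
   compare cohorts with the Epps–Singleton test, and profile where
   enhancement originates via depth-fraction bins;
7. call fold-switch candidates blindly from two independently predicted
   structures: DSSP 3-state divergence (≥15 residues at ≥50% α↔β
   difference) cross-validated by coevolution clusters (Category 1 /
   Category 2 / single-fold).

A synthetic-family generator with planted ground truth (dominant
couplings family-wide, alternative couplings confined to a
high-identity clade) makes every stage testable end to end.

## Worked example

```r
library(dualfold)

spec   <- synthetic_spec(seed = 7)   # L = 100, 2000 sequences, 15% clade
family <- generate_family(spec)

truth_map <- build_dual_fold_map(
  as_contact_sets(family$truth$dominant_pairs,    L = spec$L, id = "dominant"),
  as_contact_sets(family$truth$alternative_pairs, L = spec$L, id = "alternative"))

nested <- make_nested_msas(family$msa)
result <- run_ace(nested, reference_map = truth_map)
result
#> ace_result: L=100, 31 runs, 750 retained, eps=1, 69 clusters, 278 noise

truth_map$dominant_id <- determine_dominant(truth_map, result$superfamily_retained)
categorize_predictions(filtered_pairs(result$filtered), truth_map)
#> categorized_predictions (dominant = dominant): 8 dominant, 8 alternative,
#>   0 common, 456 unobserved
categorize_predictions(result$superfamily_retained, truth_map)
#> categorized_predictions (dominant = dominant): 8 dominant, 0 alternative,
#>   0 common, 142 unobserved
```

Reading the numbers: 31 distinct prediction runs (superfamily + 30
collapsed QID prunings) were superposed; 750 pairs (15L/2) retained;
DBSCAN at ε = 1 discarded 278 sparse pairs. The enhanced map recovers
all 8 planted dominant **and all 8 planted alternative** couplings,
whereas the superfamily-only analysis (top 3L/2 pairs of the deep MSA)
recovers the 8 dominant couplings and none of the alternative ones —
the masking-and-unmasking effect the method is built around. Correctly
predicted contacts double:

```r
amplification(8, 16)
#> [1] 100
```

and the probability of gaining the extra correct contacts by chance,
given the accompanying unobserved ones, is vanishing:

```r
hypergeom_pvalue(n_exp = 16, n_pred_super = 8, n_pred_sub = 8,
                 n_noise_super = 142, n_noise_sub = 314, L = 100)
#> [1] 1.198204e-12
```

A shell entry point wrapping the same functions ships in
`inst/scripts/ace` (subcommands `synth`, `prune`, `score`,
`import-scores`, `run`, `stats`, `blind`; every output directory gets a
JSON manifest of the configuration used).

## Further reading

The methods vignette (`vignettes/dualfold-methods.Rmd`) documents the
model and its assumptions, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and
the package's numerical conventions.
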