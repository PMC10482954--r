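---
title: "Detecting dual-fold coevolution with alternative contact enhancement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting dual-fold coevolution with alternative contact enhancement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most globular proteins fold into one stable structure, but fold-switching
(metamorphic) proteins remodel their secondary and tertiary structure and
populate two distinct folds from a single sequence. Structure predictors
that infer residue–residue contacts from multiple sequence alignments
(MSAs) almost always return only one of the two conformations: a deep
superfamily MSA is dominated by single-fold relatives, and their
coevolutionary signal masks the couplings that support the alternative
fold.

`dualfold` implements *alternative contact enhancement* (ACE), a
procedure that searches for the masked signal in protein subfamilies. The
idea is that the fold-switching variants form a clade of sequences
similar to the query, so couplings unique to the alternative fold become
visible when inference is repeated on successively more query-like
subsets of the alignment.

## The procedure

1. **Nested subfamily MSAs.** The superfamily alignment is pruned by
   sequence identity to the query (QID) over a grid of thresholds, 1% to
   50% in steps of 1%. Identity is counted over non-gap query columns;
   the query row is never removed. Thresholds yielding identical row
   sets are collapsed so no alignment is analysed twice (re-running an
   identical input would bias the z-score averages). Each alignment is
   then gap-filtered: rows with more than 25% gaps are removed first
   (never the query), then columns with more than 75% gaps. The order
   matters and is fixed — row filtering can rescue columns. A family
   enters the pipeline only if the superfamily alignment holds at least
   5·L sequences, L being the query length.

2. **Coupling inference per alignment.** Every alignment is scored by
   every configured inference method. The package ships a deterministic
   stand-in scorer — mutual information over the 21-letter alphabet (20
   amino acids + gap) with average product correction (APC) — and an
   importer for externally produced scores (pair lists or L×L matrices),
   so Markov-random-field or protein-language-model engines can be
   plugged in through files. Scores from each run are standardized to
   z-scores with the population standard deviation: the run is the
   complete population of its scored pairs.

3. **Superposition.** All runs are superposed on one contact map. Each
   pair gets the mean z-score over the runs that scored it — pairs
   absent from a run contribute nothing for that run, since zero-filling
   would systematically punish exactly the subfamily-only signals the
   method exists to find. The top ⌊15L/2⌋ pairs by mean z-score are
   retained (ties: higher support, then lower i, then lower j), in
   contrast to the 3L/2 retention customary for a single run.

4. **Density-based denoising.** Retained pairs are clustered by DBSCAN
   in the (i, j) plane (Euclidean metric, minimum cluster size 3) and
   points outside clusters are discarded as noise. The radius ε is
   chosen on an integer grid (1–15 by default; contact-map coordinates
   are integral) from an ROC against the reference contacts: moving up
   the grid, the marginal slope ΔTP/ΔFP is computed between consecutive
   radii (ΔFP = 0 counts as +∞ when TP grows, 0 otherwise), and the
   chosen radius is the largest one whose incoming slope exceeds 1 while
   the next step's slope falls below 1. A floor applies: the radius may
   not return fewer contacts than the superfamily-only baseline; when it
   would, the smallest radius meeting the baseline is used, and if none
   does, the largest grid value with a warning.

5. **Categorization.** Experimental contacts are heavy-atom pairs within
   8 Å inside a chain and 10 Å between chains, in query coordinates.
   Two conformations give a dual-fold map: common contacts (exact
   intersection), each fold's unique contacts, and per-fold interchain
   contacts. The *dominant* fold is the one whose unique contacts
   overlap more predictions from the deepest alignment — a labelling
   convention with no energetic meaning. Each filtered prediction is
   assigned by precedence common > dominant > alternative > unobserved,
   where overlap means a Chebyshev box of ±2 residues; a pair consistent
   with both folds carries no fold-discriminating information and must
   not inflate either unique count. The tolerance applies only to
   predicted-vs-experimental comparisons; the experimental common set is
   an exact intersection.

## Statistics

**Enrichment.** The probability of drawing at least the observed number
of additional correct subfamily contacts, given the additional incorrect
ones, is a one-tailed hypergeometric sum evaluated in log-space with
log-gamma binomials. The noise universe is defined as L² − N~exp~ with L
the longest experimental sequence — the squared form is retained as the
test's printed definition even though contact pairs are unordered. The
totals in the denominator default to the same quantities; an override
hook exists only because the formula names them separately.

**Cohort comparison.** Non-dominant contact fractions of fold-switching
and single-fold cohorts are compared with the Epps–Singleton two-sample
test (empirical characteristic functions at t = 0.4 and 0.8 scaled by
the pooled semi-interquartile range, biased covariance estimate, the
published small-sample correction below 25 observations, χ² p-value with
degrees of freedom equal to the covariance rank). The test is valid for
discrete data, which matters because contact fractions are ratios of
small counts.

**Depth profiles.** To ask where enhancement comes from, alignments are
binned by depth normalized to the superfamily depth, floored into
0.05-wide bins labelled by lower edge, with fraction 1 capped into bin
0.95 (so 19,050/20,000 → 0.95 and 999/20,000 → 0.00). Cumulative contact
counts are accumulated from deep to shallow — bin 0.00 contains every
alignment — and standardized per family over the twenty bins so families
with very different raw counts are comparable; a flat profile gives all
zeros by convention. One printed example in the source material
(15,100/20,000 → 0.70) is inconsistent with any uniform flooring
(15,100/20,000 = 0.755); the two self-consistent examples fix the rule
implemented here.

## Blind classification

Given structures of the same sequence from two independent predictors,
plus ACE output computed with those two structures as reference:

* **Divergence.** DSSP annotations are collapsed to three states
  (H,G,I → H; E,B → E; else C — the rule is stated in α/β terms only,
  so the standard collapse is used). A region diverges when some window
  of at least 15 residues has α↔β differences at 50% density or more;
  overlapping qualifying windows are merged and the merged span is
  trimmed to its outermost difference.
* **Corroboration.** A predicted structure is corroborated when at least
  one DBSCAN cluster (≥ 3 members) overlaps its unique contacts within
  ±2 residues. Identical predictions have empty unique sets and can
  never be corroborated.
* **Calls.** Category 1: divergent region plus corroboration of both
  structures (with exactly one corroborated the call is still emitted
  but flagged low-confidence — deliberately non-standard, covering
  partially-predicted switchers). Category 2: no divergence, but at
  least one cluster of ≥ 5 members with mean separation ≥ 6 that
  overlaps neither structure's contacts; flagged for multimer ambiguity
  because oligomeric interfaces mimic this signal, and the size/
  separation thresholds are this package's deliberately conservative
  operationalization of "substantial remaining signal". Everything else
  is called single-fold.

Positions participating only in dominant-category pairs (and in no
alternative pair) feed `mask_columns_to_alanine()`: rewriting those
columns to alanine in every row but the query weakens the dominant
signature so that a structure predictor can recover the alternative
conformation, while positions informative for both folds stay untouched.

## The synthetic generator

`generate_family()` emulates the premise under test: a superfamily in
which dominant-fold couplings are shared by everyone, while
alternative-fold couplings live only in a high-identity clade. Defaults:
L = 100, 2,000 sequences, 15% clade, 8 + 8 planted pairs, coupling
strength 0.9, background/clade identity 0.35/0.8, seed 7.

Design choices worth knowing:

* **Planted pairs form contact clusters** (an anchor column coupled to a
  run of four consecutive columns, giving four map points spaced one
  apart), because real contacts come in patches and isolated single
  pairs could never survive a minimum-cluster-size-3 density filter.
  Coupled tables use two symbol states (state 1 is the query residue)
  rather than a full Potts sampler: the mutual information is
  analytically transparent and every downstream stage is exercised.
* **Exact superfamily cancellation.** Outside the clade, the two sides
  of an alternative pair remain two-state columns but are drawn with a
  mild compensating anti-correlation chosen so the pooled superfamily
  joint distribution factorizes exactly. Alternative couplings are
  thereby a strictly subfamily-level phenomenon — the textbook picture
  the method targets — rather than merely a diluted one.
* **Identity is controlled in expectation,** not exactly; tests use
  tolerance bands. Rows are i.i.d. mutated copies of the query: no
  phylogeny, no insertions/deletions, no realistic 3-D geometry. The
  toy dual-fold maps are drawn directly as contact sets.

Consequently, passing the synthetic recovery tests shows that the
pipeline machinery does what it claims on data matching its assumptions;
it does not show that real superfamilies carry recoverable subfamily
signal — that is an empirical claim about nature, not about this code.

`generate_blind_family()` emulates the *output* scale of ACE for the
blind-classification tests: patch-shaped predicted-structure contact
sets, matching secondary-structure strings (with a 20-residue divergent
region in the dual-fold scenario), planted prediction clusters on the
patches and sparse isolated noise. The classification rules, not the
coupling inference, are the unit under test there; the full
MSA-to-category chain is exercised separately by the enhancement
recovery tests. With the built-in MI scorer, the 15L/2 retention
necessarily carries a uniform tail of several hundred noise pairs (only
~16 planted pairs exist to fill 750 slots), so spotless single-fold
specificity through the whole chain would require the unrealistically
high precision real inference engines provide; emulating the post-ACE
situation keeps the specificity property meaningful.

## Numerical choices

* MI pseudocount: a total prior mass of 1 spread uniformly over the
  joint alphabet (1/441 per joint cell, 1/21 per marginal cell), keeping
  joint and marginal smoothing consistent so an independent pair is not
  inflated by the prior. Gaps are a 21st symbol: deterministic, and
  avoids sequence-reweighting heuristics that are out of scope.
* APC means are taken over the separation-filtered pair set (default
  minimum separation 6 in query coordinates; contact maps exclude the
  near-diagonal, and the filter is configurable).
* Zero-variance score vectors z-score to all zeros with a warning;
  single-pair imported runs get z = 0 silently.
* All tie-breaks (retention, DBSCAN cluster numbering, border-point
  assignment to the first core neighbour in input order, dominant-fold
  ties to fold A with a warning) are deterministic, so identical inputs
  give byte-identical outputs.
* Chain-to-query mapping uses global alignment with match +1, mismatch
  0, gap open −5, gap extend −1, refusing mappings under 15% identity
  (almost certainly the wrong chain).
* Structures: hydrogens, waters and HETATM records are dropped; among
  altlocs the highest-occupancy conformer is kept (ties alphabetically).

## Problem sizes in the test suite

The suite runs the full pipeline on ten replicate synthetic families at
the default specification, twenty single-fold and ten dual-fold blind
scenarios, 1,000 exact-arithmetic checks of the enrichment p-value, 100
randomized DBSCAN instances of up to 500 points, and a 1,000-replicate
null calibration of the Epps–Singleton test — sizes chosen so the whole
suite completes in a couple of minutes on one core while still
exercising every stage at the generator's default study conditions.

## Known limitations

* The stand-in MI scorer is a transparent baseline, not a substitute
  for MRF or language-model inference; on real families its top-15L/2
  precision is far lower, so external score files are the intended
  production path.
* Whether the two inference methods should be z-scored jointly or per
  run is not prescribed by the procedure; this package standardizes per
  run (per alignment × per method) and treats the choice as a
  sensitivity-analysis knob.
* Oligomer handling folds interchain contacts into each fold's unique
  set for categorization; no biological-assembly reconstruction from
  symmetry operators is attempted, and no structure superposition or
  RMSD is computed.
* The enrichment test's L² noise universe follows the printed
  definition; with unordered pairs it roughly doubles the noise count,
  making reported p-values conservative in a uniform way.
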