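---
title: "Methods: screening intronic variants for splicing errors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening intronic variants for splicing errors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicescreen)
```

## The problem

A large fraction of disease-associated genetic variants act by disrupting
pre-mRNA splicing rather than by changing protein sequence. Variants near
intron/exon boundaries are especially hard to interpret: splicing signals —
the 5' splice site (donor), the branch site with its downstream
polypyrimidine tract, and the 3' splice site (acceptor) — are short,
degenerate, and partially redundant. splicescreen implements a transparent,
feature-based screen for such variants: every input SNV is triaged by its
position relative to the nearest intron, described by a vector of
biophysically interpretable features, and scored by a route-specific
L1-penalized logistic model whose coefficients can be read directly.

## Triage: windows and routes

Positions are expressed in transcript orientation as offsets from the two
intron ends. At the donor end, `+1` is the first intronic base and `-1`
the last base of the upstream exon; at the acceptor end `-1` is the last
intronic base (the acceptor G). The screen considers:

* **5'ss route**: offsets `-3` to `+30` around the donor (inclusive,
  spanning the junction);
* **3'ss routes**: offsets `-78` to `-4` from the acceptor (inclusive,
  wholly intronic). A substitution here that creates an AG dinucleotide on
  the transcript strand — absent from the reference — goes to the
  dedicated **novel-AG** model, because an intronic AG between branchpoint
  and acceptor can hijack 3'ss selection; all other acceptor-window
  variants go to the **non-AG** model.

Everything else (indels, intergenic variants, reference mismatches,
intragenic variants outside both windows, deep-intronic positions) is kept
in the output with its basic gene/intron annotation but never scored.
Two boundary readings were genuinely open and are resolved as follows: the
donor window's `-3` counts exonic bases (the junction-spanning reading);
and acceptor offsets `-3..-1` — the acceptor AG and the `-3` base — are
excluded from all models, exactly as the `-78..-4` window implies.

Ties are deterministic: when a variant qualifies for both windows (possible
only in introns shorter than 108 bp) the donor route wins; among equidistant
introns the lower genomic start wins. Variants hitting qualifying introns of
several transcripts produce one row per distinct intron interval, with a
multiplicity count, because no canonical-transcript rule is imposed.

## Features

For each routed variant the package computes reference-allele and
alternative-allele values (plus `alt - ref` deltas) of:

| feature | meaning | window (defaults) |
|---|---|---|
| `distance_to_site` | signed offset to the route's splice site | — |
| `conservation` | mean per-base conservation probability | 7 nt centered on the variant |
| `u2_mfe_*` | nearest-neighbor duplex energy of the U2 snRNA recognition sequence `GUAGUA` against the branch region (kcal/mol) | acceptor offsets −50..−10 |
| `fold_dG_*` | minimum free energy of local RNA secondary structure (RNAfold) | variant ± 35 nt, transcript strand |
| `openness_*` | equilibrium probability that a span around the variant is unpaired (RNAplfold) | 11 nt span |
| `py_tract_*`, `py_run_*` | pyrimidine fraction and longest pyrimidine run | acceptor offsets −25..−5 |
| `site_strength_*` | log2-odds of the junction window under a PWM estimated from all annotated sites | donor −3..+6, acceptor −20..+3 |
| `novel_ag_flag`, `novel_ag_to_canonical_dist` | novel-AG creation and its offset gap to the canonical acceptor AG | acceptor window |

Window defaults bracket the acceptor triage window; they are fixed in
`feature_config()` and can be changed without touching code. The branch
window (−50..−10) covers the empirical branchpoint distribution; the
Py-tract window (−25..−5) sits between branchpoint and acceptor. The U2
register is configurable (`GUAGUA` by default; the longer
`GUAGUACUA` register or G-U wobble pairing can be enabled) since the
exact register is not standardized. The U2 duplex score is a deliberately
simple stacking-sum model over ungapped alignments using the Turner 2004
Watson-Crick stack table: maximal runs of two or more consecutive pairs
contribute their summed stack energies and the best run over all
alignments is returned. It is monotone under context extension and exactly
hand-checkable, which we value over the marginal realism of a full duplex
folding model with loop penalties.

Missing conservation imputes 0 — unobserved is not evidence of
conservation — with an indicator feature (`cons_imputed`) carrying the
missingness information. Conservation enters both as a window mean and,
implicitly through the window of width 1, as the variant-base score; the
penalized fit decides what to keep. Any feature-level failure flags the
row (`feature_ok = FALSE`), imputes zeros so matrices stay complete, and
the variant is emitted unscored.

All windows are defined in transcript orientation, which makes the entire
feature vector invariant under reverse-complementing the genome and
flipping annotation strands; this is property-tested to 1e-9.

## The penalized logistic model

Each route has its own model (donor and acceptor recognition involve
different snRNP machinery, and novel-AG competition is a different decision
problem), fitted independently:

$$\log \frac{P(Y_i = 1)}{1 - P(Y_i=1)} = \beta_0 + \sum_{j=1}^p \beta_j X_{ji}$$

with an L1 penalty $\lambda \sum_j |\beta_j|$ on the slopes (intercept
unpenalized), minimized by cyclic coordinate descent on the IRLS quadratic
approximation. Features are standardized to zero mean and unit (1/n)
variance inside the fit; coefficients are stored on the standardized scale
together with the transform, so the penalty treats features comparably
regardless of units.

Numerical choices: IRLS weights are floored at 1e-5; convergence is
declared when the maximum coefficient change falls below `tol` (1e-7) or
the penalized objective stops improving in relative terms (1e-9) — the
latter terminates cleanly on separable data where coefficients diverge
logarithmically; the soft-threshold operator has a relative dead-zone of
1e-12 so that at $\lambda = \lambda_{\max}$ the KKT zero solution is exact
in floating point. Cross-validation path fits additionally stop refining a
$\lambda$ once the linear predictor saturates (|η| > 30), where further
coefficient growth cannot move held-out deviance.

The penalty is chosen at the minimum of stratified 10-fold cross-validated
binomial deviance over 100 log-spaced values from $\lambda_{\max}$ down to
$10^{-4}\lambda_{\max}$, ties resolved toward the larger (sparser)
penalty; the fold assignment is deterministic under the stored seed
(default 20240615). Minimal-deviance selection is the package's canonical
rule; it is worth knowing that this rule is statistically permissive — at
the deviance minimum the lasso typically retains a few small-magnitude
noise coefficients alongside the true signal, a well-documented property
of CV-min selection shared by reference implementations. The acceptance
script therefore reports both strict support recovery (true support, correct
signs, at most two spurious features) and sign/support recovery without
the sparsity bound.

The decision cutoff is chosen on training scores by maximizing Youden's
J (sensitivity + specificity − 1) over midpoints of consecutive sorted
unique scores, ties resolved toward the lower threshold (favoring
sensitivity). Classification is boundary-inclusive: `score >= cutoff` is
called significant. The shipped default models are untrained placeholders
that exist to carry the published decision cutoffs (0.13 for 5'ss,
0.1837238 for novel-AG, 0.07784796 for non-AG) and make the pipeline
runnable end to end; whether such cutoffs were derived on training or
held-out data is not recorded with them, and retraining always recomputes
the cutoff with `select_cutoff()`. Class imbalance is handled by the plain
unweighted deviance, as the model formula states.

## The synthetic assay generator

Real training data for this kind of model comes from massively parallel
splicing assays: thousands of ref/alt oligo pairs in three-exon minigenes,
read out as spliced vs unspliced amplicon counts and tested pair-by-pair
with Fisher's exact test. `simulate_pairs()` emulates exactly that
structure at reduced scale: 2,000 pairs by default (the real assay's ~11k
pairs scaled down for desk runtime — same structure, minutes not hours),
reference PSI drawn from Beta(2,2), mean Poisson depth 200 reads per
construct, 20% of pairs truly splice-altering with logit-PSI shifts of
|N(2, 0.5)| and random sign. These values are the generator's fixed study
conditions: a PSI spectrum covering weak to strong splicing, depths at
which a shift of ~2 logits is comfortably detectable, and a minority of
true effects, as in disease-variant collections.

Labeling uses the two-sided Fisher exact test under the
probability-ordering convention (the most common definition; sidedness is
otherwise unstated) and Benjamini-Hochberg correction at 0.05 by default —
with thousands of simultaneous tests uncorrected labeling would be
implausible, though the correction actually used by any given assay is an
assumption and is documented as such (`correction = "none"` is available).

`make_toy_locus()` generates the fixture genome: a 2.4 kb contig with one
three-exon gene per strand, 200 bp introns with consensus donors, a
planted `TACTAAC` branch motif, a polypyrimidine tract, an AG-free
acceptor window, and a scripted VCF covering every triage route.
`synth_training_set()` plants random SNVs in the routed windows, computes
their real feature vectors, and draws labels from a known sparse logistic
truth (defaults: splice-site weakening, conservation, and U2-pairing loss
drive the altering probability) so support recovery can be verified
against stored truth.

What passing these tests shows — and does not. The generator reproduces
the count structure, the test statistics, and the feature-label coupling
of the assay; it deliberately omits sequencing error, PCR jackpotting,
ligation bias, construct-context effects, and any tissue-specific
regulation. Green tests demonstrate that the machinery is correct, not
that the shipped placeholder models are accurate on real genomes; for real
use, retrain on real labeled variants.

## Evaluation

`confusion()` and the metric functions reproduce the standard definitions
(sensitivity, specificity, accuracy as percentages; F-measure as
2PR/(P+R), defined 0 when no true positives). Display rounding is one
decimal; raw values are kept unrounded. Undefined ratios (zero
denominators) return `NA` rather than a number.

## Problem sizes

The test suite and acceptance script run the toy locus (2.4 kb, 4 introns,
~10-150 variants), Fisher exactness over all 2x2 tables with n ≤ 40,
penalty-recovery simulations at n = 2000, p = 10 over 10 seeds, and null
calibration at 2,000 pairs — sizes chosen so a complete desk run finishes
in minutes while every property is exercised at scale sufficient for its
statistical assertion.

## Known limitations

* Only SNVs are scored; indels are triaged out by design.
* Deep-intronic and exonic-body variants are out of the screen's windows.
* Predictions are not tissue-specific: every feature is a property of the
  pre-mRNA sequence and its annotation.
* The shipped models are placeholders carrying published cutoffs; scores
  from them are uninformative (0.5) until retrained.
* Branchpoint annotation ingests experimental and precomputed predicted
  records; it does not predict branchpoints de novo.
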