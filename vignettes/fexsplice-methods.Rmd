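---
title: "Predicting splicing disruption by first-exon-nucleotide variants: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting splicing disruption by first-exon-nucleotide variants: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fexsplice)
```

## Background and model

Most internal exons begin with G. That G is simultaneously a coding base
and the terminal base of the 3′ splice-site AG read by U2AF35, so a
substitution there (a Fex-SNV) can silently break splicing while databases
record it as missense. Whether it does depends on the acceptor's
AG-dependence: a long, pyrimidine-rich tract (PPT) lets U2AF65 anchor the
spliceosome on its own, making the site insensitive; a short or degenerate
tract leaves recognition dependent on U2AF35 contacting the boundary AG—G,
and vulnerable. Mutagenesis places the insensitivity boundary at a
contiguous pyrimidine stretch of roughly 10–15 nt.

The package casts the call as supervised classification over 115
hand-engineered cis-element features of the variant-applied sequence
context, with gradient boosting as the primary learner. The pipeline is:
context extraction → feature extraction → training/cross-validation →
recursive feature elimination → thresholded classification.

## Sequence context conventions

All sequences are transcript-oriented; minus-strand exons are
reverse-complemented so positions can always be written Int−k (intron,
counting back from the junction) and Ex+k (exon). A context stores
Int−50..Int−1, the exon from Ex+1 (capped at 100 nt for motif scanning —
the true length is its own feature), and the 9-nt donor window (last 3
exonic + first 6 intronic nt).

Decisions where the underlying methods are silent:

- **Terminal exons are rejected**, not scored: they lack the flanking
  intron the features need.
- **Exons shorter than 3 nt**: the donor window and the Ex+1..Ex+3
  positional indicators continue into the downstream intron, which keeps
  every feature defined and makes the variant base enter the donor window
  when the exon is ≤ 3 nt. This is a deterministic convention for a case
  the source methods never discuss.
- **Ambiguity bases (N)** in any required window are a hard error.
  Imputing them would silently corrupt features.
- Overlapping transcripts sharing a coordinate are all reported; no
  deduplication.

## Feature definitions

**Branch point.** The best yUnAy match is searched among all 5-mers wholly
within Int−50..Int−3, with the branch A at window position 4 as a hard
constraint; the conserved-A "found" flag is itself a feature. Ties break
toward the acceptor, where functional branch points usually sit. When no
candidate exists the score is floored at (minimum achievable PWM score − 1),
keeping the feature numeric and rank-consistent below every real score. The
branch-to-acceptor distance is included as a third feature; it is a
reconstruction the source feature list does not spell out, and is flagged
as such here.

**PPT.** The tract is anchored biologically: one base 3′ of the branch A
through Int−3. Without a branch point the fallback window Int−20..Int−3 is
used. Features: length, longest contiguous C/T run, ratios of T, G,
purines and pyrimidines, and presence of GGG (an hnRNP H/K attractor).

**Positional indicators.** One-hot bases at Int−7, Int−6, Int−5, Int−3 and
Ex+1..Ex+3, computed on the **variant allele** — "T at Ex+1" can only rank
as a feature under variant-allele encoding. With four intronic positions
this gives 16 intronic + 12 exonic indicators; reports of the original
feature set are internally inconsistent about that split (12 + 12 in one
place, four named intronic positions in another), and this registry keeps
the 16-indicator reading, which reconciles with the named positions.

**Site scores.** Shapiro–Senapathy (windows: Int−13..Ex+1 acceptor,
3 exonic + 6 intronic donor), maximum-entropy log₂-odds (Int−20..Ex+3
acceptor, 9-nt donor), SD-score (donor). All scorers consume the
variant-applied sequence, so acceptor scores respond to the alternate
allele — otherwise per-allele predictions would be impossible. A pseudocount
of 1e−4 is applied to frequency tables at load; the branch-point PWM uses
0.001.

**RBP motif sums.** For each of 71 RBPs, the signed sum of motif scores
over every match start (overlaps count independently), scanned over
Int−50..Int−1 and Ex+1..Ex+50 as two windows so a motif never straddles
the junction. Signed summation (enhancers positive, silencers negative) is
a documented choice; the original feature may have kept separate sums.

The registry totals 115 = 71 + 28 + 5 + 7 + 3 + 1. The per-group counts are
a reconstruction that reconciles every named feature with the printed
total; the registry is data-driven so alternative decompositions load from
a file.

## Packaged resources are synthetic

The branch-point PWM, splice-site frequency matrices, SD-score table,
MaxEnt-layout parameter sets and the 71-RBP motif table shipped under
`inst/extdata/resources/` are consensus-shaped synthetic reconstructions
(filenames carry `_synthetic`). They make the machinery fully testable and
give realistic score distributions, but they are not the published tables;
users retraining on real variants should substitute genuine exports, which
load through the same documented layouts. The packaged MaxEnt parameter
sets use a per-position decomposition; the loader and scorer support the
full product/quotient sub-table structure of published maximum-entropy
splice models, and the tests exercise overlapping sub-tables with
denominator corrections.

## Classifiers and evaluation

Gradient boosting is the primary model, with linear-SVM and random-forest
baselines. Hyperparameters keep the boosting-family vocabulary
(`learning_rate`, `num_leaves`, `n_estimators`, `min_child_samples`) and
translate onto the xgboost backend (`eta`, `max_leaves` with loss-guided
growth, `nrounds`; `min_child_samples` maps to `min_child_weight` divided
by 4 because each sample contributes at most ¼ to the logistic hessian).
Default grids are deliberately small — e.g. learning rate {0.05, 0.1},
leaves {7, 15, 31}, rounds {100, 300}, minimum child samples {5, 10} —
honest for a dataset of a few hundred rows; grid search selects by inner
5-fold mean AUROC.

Evaluation reports the seven statistics (accuracy, precision, recall,
specificity, F1, NPV, MCC) from per-fold confusion counts at the 0.5
threshold, plus AUROC (rank-based Mann–Whitney, ties ½) and AUPRC (step
integration over descending distinct thresholds). Mean ± SD are computed
over per-fold values; pooled curves are exported separately, with the
0.5-threshold operating point marked on each. A statistic whose
denominator is zero is reported as undefined (`NA`), never as 0.

Recursive feature elimination drops the lowest-importance feature
(split-gain for boosting) one at a time, scoring every subset by LOOCV
**balanced** accuracy — the stated selection criterion, even though plain
accuracy is what the headline table reports — and returns the
balanced-accuracy argmax, ties to the smaller subset.

Classification uses the inclusive threshold: probability ≥ 0.5 ⇒
splicing-affecting. Trained boosting models serialise to a versioned JSON
container embedding the registry hash; prediction refuses a vector whose
registry hash differs.

## The synthetic-data generator

The generator emulates the AG-dependence mechanism, not the real curated
dataset. Each record is an internal exon (index 2 of 3) on its own
chromosome: 25% GC-balanced intron background, acceptor ending AG, donor
starting GT with a consensus-leaning extension, exon starting G. Planted
elements: a yUnAy branch window (consensus concentration 0.85), and a
contiguous pyrimidine run ending at Int−3 — 4–9 nt with tract background
pyrimidine fraction 0.45 for the affecting class, 15–30 nt over fraction
0.65 for the neutral class, T:C at 0.8 within planted pyrimidines. The
mechanism label is `affecting` iff the run is < 12 nt (the centre of the
quoted 10–15 nt window); 5% of labels are then flipped as annotation
noise. Purine flanks and a run-capping repair pass guarantee the realized
longest run equals the planted one, so the truth sidecar is exact. A
quarter of records are placed on the minus strand to exercise
reverse-complement handling.

What the generator does **not** emulate: real class-conditional feature
distributions, linkage between tract strength and branch-point strength,
genuine RBP motif enrichment differences between classes, or curation
biases of literature-derived labels. Passing tests therefore demonstrate
that the pipeline recovers a planted mechanism through the full
genome→features→model path — not that the packaged defaults reproduce
real-data performance, which requires the curated SNV list and genuine
resource tables.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the generator at 500
variants for cross-validation (10-fold, fixed seed) and use 60 rows × 115
features for the elimination study; element-detection oracles run on 1,000
random windows. These sizes were chosen so the full mechanism-recovery
claim is exercised while the suite stays quick to run routinely. Fold
assignment is stratified and seeded; all RNG flows through a single seed
argument per entry point, and seeded runs are reproducible bit for bit.
Ties in branch-point search break toward the acceptor; ties in feature
elimination drop the earliest-registered feature; ties in subset selection
prefer fewer features.

## Known limitations

- Packaged resource tables are synthetic; absolute score values are not
  comparable to the published scorers until genuine tables are substituted.
- Only the acceptor-proximal mechanism is modelled; deep-intronic or
  exonic-splicing-enhancer-driven effects beyond the scanned windows are
  out of reach.
- The feature-group decomposition of the 115-feature registry is a
  documented reconstruction.
- Real-data headline numbers (e.g. 15-feature AUROC ≈ 0.86) require the
  curated variant list and GRCh37 sequence; the package ships the recipe,
  not the data.
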