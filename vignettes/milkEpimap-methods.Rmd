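---
title: "Epitope mapping and tolerance prediction for cow's milk allergy: methods and design"
author: "milkEpimap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epitope mapping and tolerance prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkEpimap)
```

## The problem

IgE-mediated cow's milk allergy (CMA) is the most common food allergy of
infancy and is usually transient: most children become clinically
tolerant within a few years, while a minority remain allergic and tend
to have more severe disease. Antibody binding to *linear* (sequential)
B-cell epitopes of the five major milk allergens — αS1-, αS2-, β- and
κ-casein and β-lactoglobulin — can be interrogated at scale with
overlapping-peptide microarrays, and the resulting IgE/IgG4 binding
profiles carry prognostic information about who will outgrow the
allergy. `milkEpimap` implements the complete analysis chain for this
kind of longitudinal study: peptide library design, spot-level
normalization, epitope calling, group comparison, clustering, and
gradient-boosted prediction of later tolerance from baseline data —
together with a synthetic study generator so that every step can be
exercised and validated without patient data.

## Peptide tiling

Each mature allergen chain is tiled into 20-residue peptides at a
3-residue offset. Windows start at positions 1, 1+3, 1+6, … while they
fit; when the last regular window stops short of the C-terminus one
additional peptide covering the final 20 residues is appended, so the
tiling always ends flush with the protein. For a chain of length $L$
the peptide count is

$$ n(L) = \left\lfloor \frac{L-20}{3} \right\rfloor + 1 +
   \mathbf{1}\!\left[(L-20) \bmod 3 \neq 0\right]. $$

Applied to the bundled mature chains (199, 207, 209, 169 and 162
residues) this yields 61, 64, 64, 51 and 49 peptides — 289 in all.
The bundled FASTA contains canonical-sequence reconstructions of the
mature chains (signal peptides removed, UniProt entries
P02662/P02663/P02666/P02668/P02754); no accessions are attached to the
array itself, so the fixture choice is inferred from the fact that
exactly these chain lengths reproduce the per-protein peptide counts
under the tiling rule. Users with a different isoform in mind can
supply their own FASTA. Peptides are indexed 1-based within each
protein, and all coordinates in the package are 1-based inclusive;
epitope regions are named in the field's convention, e.g.
`κ-cas 29–31`.

## Spot normalization and positivity

Each array carries every peptide in duplicate plus four PBS
negative-control spots. Normalization is strictly per array (each
patient × visit × isotype carries its own controls): the PBS spots
define a location and scale — by default their mean and *population*
standard deviation (divisor $n$); a `robust` switch substitutes
median/MAD — and every replicate spot is standardized as
$z = (I - \mathrm{location})/\mathrm{scale}$. The *weighted average
Z-score* of a peptide is the quality-weighted mean of its replicate
Z-scores, with weight 1 for usable spots and 0 for flagged ones; a
peptide with no usable replicate becomes a missing cell. Arrays with
fewer than two usable PBS spots, or with zero control spread, are
rejected rather than normalized.

A peptide is **positive** when its weighted average Z-score *exceeds*
three — strictly, so $z = 3$ is negative. From the calls come the two
study variables: **intensity**, the mean Z-score over a protein's
peptides, and **diversity**, the count of positive peptides. Missing
cells are excluded from both, and a missing call contributes to
neither numerator nor denominator downstream.

## Informative epitopes and group comparisons

A peptide is an **informative epitope** at a visit when more than 75%
(strictly) of the allergic patients at that visit recognize it;
allergic patients with a missing call for that peptide are excluded
from its denominator. Runs of consecutive informative peptide indices
within a protein merge into a single named region; the region's
reported fraction is the minimum over its members. Peptides
informative at *every* visit form the persistent epitope set.

Allergic-versus-tolerant differences in intensity and diversity are
tested per protein × isotype with a two-sided Mann–Whitney test and
Benjamini–Hochberg adjustment across the comparison family at the
visit. The summaries are skewed and group sizes modest, which is why a
rank test rather than a t-test is the default; both the test family
and the α level are visible in the interface. At the baseline visit
every patient is still allergic, so baseline groups are formed by the
6-month accumulative-tolerance outcome. Patients who withdraw
contribute to the visits they attended and are absent afterwards;
once a patient tolerates milk they leave follow-up but remain
"tolerant" under accumulative labelling at every later target.

## Clustering

Patient binding profiles are clustered with average linkage (UPGMA) on
the Pearson correlation distance $d = 1 - r$, computed over
pairwise-complete cells. Patients with under 50% usable cells are
excluded with a warning, and a constant profile (zero variance) is an
error rather than a silent `NA`. Only the patient axis is clustered;
peptides stay in library order so that heatmap columns remain
anatomically interpretable. Figure artifacts use a diverging colour
scale clipped to $Z \in [-3, 10]$ (clipping affects the image only;
the numbers are always emitted as TSV alongside, bit-identical across
runs). Dendrograms export to newick via `ape`.

## Tolerance prediction

The model inputs are strictly baseline: the eight serology
determinations (total IgE and sIgE to whole milk, α-lactalbumin,
β-lactoglobulin, casein, in kU/L; sIgG4 to casein, β-lactoglobulin,
α-lactalbumin, in mg/L) plus the visit-1 IgE and IgG4 Z-scores of all
289 peptides — 586 features. All peptides enter by default rather
than only the informative subset, because importance rankings can
legitimately surface peptides outside the informative set;
`buildFeatureTable(peptideSubset = ...)` restricts the features when a
leaner model is wanted. Outcomes are accumulative-tolerance labels at
target visit 2, 3 or 4; targets 5 and 6 are refused by default because
too few patients remain allergic that late to learn from.

The protocol is: stratified 70/30 train/test split; stratified
ten-fold cross-validated grid search on the training set over boosted
tree hyperparameters (depth 2–4, learning rate 0.05–0.3, minimum
child weight 1 or 5, 50–300 trees), maximizing F1 at the 0.5
probability threshold with "tolerant" as the positive class; refit on
the full training set with the winning configuration (ties resolve to
the first configuration in grid order, making the search
deterministic); evaluation on the held-out test set by ROC AUC and
confusion-matrix metrics at 0.5. Class imbalance is absorbed by
`scale_pos_weight` equal to the training class ratio, and missing
feature values are imputed with training-split medians only — the test
split never influences imputation. The grid is a configuration choice,
not a reproduction: the study protocol it follows fixes the search
*procedure* (grid search, ten-fold CV, F1 objective) but not the grid
itself. A single seed drives split, folds and fits, so a report is
bit-reproducible. Variable importance is gain share; the top-k report
renormalizes over the reported rows and labels the column accordingly.

AUC is computed with a fixed direction (tolerant predicted by larger
scores), so a permuted-label model is free to score *below* 0.5 —
important when checking that the null pipeline is centred at chance
rather than optimistically folded above it.

## The synthetic study generator

The generator produces the complete input universe of such a study —
cohort flow, baseline serology, and raw spot-level arrays — with a
ground-truth ledger for every planted feature, so recovery can be
scored exactly.

**Cohort flow.** 118 patients enrol allergic. Before each follow-up
visit a still-allergic patient withdraws with probability 0.11;
otherwise they convert to tolerance with that visit's probability
(0.407, 0.354, 0.222, 0.222, 0.071 at visits 2–6), modulated on the
logit scale by a per-patient latent propensity. The withdrawal rate
was chosen analytically so that the expected end-of-study composition
is ≈76 tolerant / 13 allergic / 29 lost of 118, matching the study
flow the defaults emulate. The published per-visit tolerance
percentages are interpreted as conversion probabilities among
still-allergic attendees; other denominator conventions exist, and the
config exposes the probabilities directly rather than claiming to
resolve that ambiguity.

**Serology.** Each marker is log-normal with parameters solved from
its published baseline median and IQR ($\mu = \log m$,
$\sigma = \log(q_{3}/q_{1})/(2\,\Phi^{-1}(0.75))$), chosen because the
published IQRs are strongly right-skewed. Whole-milk sIgE is
correlated (ρ = 0.5 on the log scale) with the negative tolerance
propensity — higher baseline sIgE, later tolerance — giving baseline
features a modest, non-trivial association with outcome.

**Arrays.** PBS spots draw from the background distribution
(mean 200, SD 50 a.u.); peptide spots add a Z-scale signal times the
background SD, with multiplicative log-normal replicate noise. Null
peptides carry latent Z spread 0.7, which places their measured
false-positive rate at ≈5% above Z = 3; the floor is dominated not by
the latent spread but by re-estimating the control scale from only
four PBS spots per array, whose reciprocal is heavy-tailed — a
property any four-control layout shares, and a deliberate realism.
The four persistent epitope regions (αs1-cas 3, αs1-cas 16–18,
κ-cas 29–31, β-lac 37–39; ten peptides) are planted: each patient's
recognition of each planted peptide is drawn once (default
probability 0.97) and persists across visits; recognized peptides sit
at Z 6–10 while the patient is allergic and fade to 30% after
tolerance. The default was set at 0.97 by a binomial-tail argument:
the smallest allergic group the flow produces (~13 patients at visit
6) must still exceed the strict 75% recognition cut-off with high
probability for every member peptide of every region. From visit 2
on, allergic patients bind the three effect-carrying caseins 1.5 Z
units more intensely and gain an 8% per-peptide chance of an extra
positive; IgG4 is generated as a 0.5-attenuated copy of the IgE
scale, which makes IgG4 informative epitopes rare while preserving
IgG4 intensity/diversity group differences — the qualitative pattern
such cohorts show. The baseline visit carries *no* group effect in
the faithful preset; a configurable baseline shift on the planted
peptides exists for model validation (a shift of twice the Z spread
plants a d ≈ 2 effect on ten features), and `plantedFeatureTable()`
plants the same effect directly on the feature scale, bypassing the
array noise, for clean trainer validation. An optional
`recognitionSlope` links planted recognition to low tolerance
propensity (persistent recognition tracking persistent allergy); it
is off by default because it would leak a small group difference into
the baseline visit, which the faithful preset keeps exactly null.

**What the generator does not emulate.** Batch and scanner effects,
spatial spot artifacts, isotype cross-talk, serial correlation of
serology across visits, and the real cohort's visit-specific
informative-epitope counts. Passing recovery tests therefore shows
that the pipeline's logic is correct under the assumed generative
structure, not that any particular clinical result is reproduced —
the real study's patient-level data are not public, and its headline
AUCs and epitope counts are explicitly out of reach at desk scale.

## Numerical choices and degenerate inputs

* Population (divisor-$n$) SD for controls: four spots are a sample of
  a printed layout, not of a population of arrays; the choice is
  documented and the robust switch sidesteps it entirely.
* Strict inequalities at both decision points (Z > 3, fraction >
  0.75); boundary cases are covered by tests.
* All-tied group comparisons return p = 1 rather than `NaN`.
* Grid-search ties resolve to the first configuration in grid order.
* Degenerate arrays (no PBS spread, < 2 usable controls), constant
  clustering profiles, single-class training outcomes, and planted
  peptides missing from the library are errors, not warnings.

## Problem sizes used by the test suite

The suite validates oracle equivalence on 100 random fixtures per
operation, baseline null behaviour on 200 regenerated studies,
permuted-label behaviour over 20 seeds, and planted-signal recovery on
full six-visit studies; the model checks run a deliberately small
hyperparameter grid, since the sanity properties under test (chance
AUC under permutation, near-perfect AUC under strong planted signal)
are insensitive to the grid. These sizes were chosen as the smallest
that make the stochastic assertions stable across seeds.

## A worked end-to-end run

```{r example, eval = FALSE}
lib <- buildLibrary()                      # 61/64/64/51/49 peptides
study <- simulateStudy(library = lib, seed = 1)

bmE1 <- buildBindingMatrix(study$spots, lib, "IgE", visit = 1)
inf1 <- informativePeptides(bmE1, study$labels, visit = 1)
mergeContiguous(inf1, lib)                 # named epitope regions

perVisit <- lapply(1:6, function(v)
  informativePeptides(buildBindingMatrix(study$spots, lib, "IgE", v),
                      study$labels, v))
persistentEpitopes(perVisit, lib)          # the four planted regions

ft <- buildFeatureTable(study$cohort,
                        list(IgE  = bmE1,
                             IgG4 = buildBindingMatrix(study$spots, lib,
                                                       "IgG4", 1)),
                        targetVisit = 2)
trainEvaluate(ft, targetVisit = 2, seed = 1)
```
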