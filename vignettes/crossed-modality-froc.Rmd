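---
title: "Crossed-modality JAFROC analysis: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crossed-modality JAFROC analysis: models, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossfroc)
library(dplyr)
```

## The problem

In a free-response (FROC) observer study the reader marks every suspicious
location on an image and rates their confidence; a case can yield zero, one,
or many marks. Scoring against a truth table turns each mark into a lesion
localization (LL: within an acceptance radius of a true lesion) or a
non-lesion localization (NL: everything else). This paradigm credits
*finding the right thing in the right place*, which is why it carries more
statistical power than case-level ROC analysis for detection tasks.

`crossfroc` analyses FROC studies in which the imaging condition is defined
by **two fully crossed factors** — the motivating design is CT exposure
(four mAs levels) crossed with image reconstruction (filtered back
projection vs iterative reconstruction), read by eleven observers on 34
normal and 34 abnormal sections of a thorax phantom. A conventional
single-factor analysis would treat the 4 x 2 = 8 conditions as unstructured
modalities and burn power on 28 pairwise comparisons; the crossed procedure
asks the two questions that matter (is there an exposure effect? a
reconstruction effect?) with 6 + 1 comparisons.

## Figures of merit

The primary figure of merit is the equally weighted JAFROC (wAFROC) FOM.
For one design cell (one factor-level pair and one reader),

$$\theta = \frac{1}{K_1 K_2} \sum_{n=1}^{K_1} \sum_{a=1}^{K_2}
  \sum_{l \in a} W_{al}\,\psi(LL_{al},\, FP_n),$$

where $FP_n$ is the highest NL rating on normal case $n$, $LL_{al}$ the
rating of lesion $l$ of abnormal case $a$, the kernel $\psi$ scores 1 / 0.5
/ 0 for win / tie / loss, and the weights $W_{al} = 1/n_{lesions}(a)$ sum
to one per case so that every abnormal case counts equally regardless of
its lesion count. $\theta$ is the weighted empirical probability that a
lesion rating beats the highest rating on a normal case; it ranges over
$[0, 1]$ with 0.5 at chance. Only normal cases contribute false positives;
NLs on abnormal cases do not enter the wAFROC.

For consistency checking, the highest-rating inferred-ROC FOM reduces each
case to its single highest rating (NL or LL) and computes the Wilcoxon
ROC area; for observers at or above chance it lives in $[0.5, 1]$, so its
intertreatment differences are compressed relative to wAFROC differences.

Three conventions needed fixing that the FOM definition alone does not pin
down:

* **Unmarked entities** carry the sentinel $-\infty$, strictly below any
  legal rating, so the same $\psi$ kernel handles marked and unmarked
  entities uniformly.
* **Ties**, including the (unmarked, unmarked) pair, score 0.5. This is the
  symmetric empirical-probability convention: an observer who marks nothing
  at all scores exactly 0.5. The `tie` argument of [fom_matrix()] exposes
  the alternative (e.g. `tie = 0` floors unmarked-lesion contributions); all
  shipped analyses use 0.5.
* **FOMs are invariant under any strictly increasing transform of the
  ratings** (only order enters $\psi$); the test suite asserts this, and it
  is why integer 1-10 and continuous ratings can be mixed freely.

## Significance testing

Per-cell FOMs form a treatment x reader table analysed with the
Obuchowski-Rockette model with Hillis's modifications. Because the phantom
is a single physical object, the case set is treated as **fixed** and the
readers as random (RRFC):

$$F = \frac{MS(T)}{MS(TR)} \sim F_{I-1,\,(I-1)(J-1)},$$

with pairwise treatment differences tested by
$t = (\bar\theta_{i\cdot}-\bar\theta_{i'\cdot})/\sqrt{2\,MS(TR)/J}$ on the
same denominator df, and CIs dual to the tests (a CI excludes zero exactly
when $p < \alpha$). The random-reader random-case generalization
(`rrrc_analysis()`) is included for completeness: its denominator is
$MS(TR) + J\max(Cov_2 - Cov_3, 0)$ with Hillis denominator df, where the
covariance components come from leave-one-case-out jackknifing
(`jackknife_foms()`, `jackknife_covariances()`). Raw covariance estimates
may be negative and are reported untruncated; the truncation lives only in
the denominator.

The **crossed-modality procedure** (`crossed_modality_analysis()`) runs two
sequential single-factor RRFC analyses: factor 1 on FOMs averaged over
factor 2 ($\theta_{i_1 \cdot j}$), and factor 2 on FOMs averaged over
factor 1. Averaging happens on FOMs, not ratings — the dot-notation
quantity the procedure is defined on. Each analysis is tested at the
Bonferroni-corrected threshold $\alpha/2 = 0.025$, holding the family-wise
type-I error at $\alpha = 0.05$ conservatively, and within each analysis a
pair is declared significant only when the overall $F$ test *and* the
pairwise $t$ test both pass (the protected rule).

Two exact identities tie this together and are asserted in the tests:

* For a 4 x 2 x 11 design the two analyses have df $(3, 30)$ and $(1, 10)$
  by construction.
* Pseudovalues $Y_k = K\theta - (K-1)\theta_{(k)}$ are linear in $\theta$,
  so averaging pseudovalues over a factor is identical to jackknifing the
  factor-averaged FOM; either implementation of the crossed procedure's
  resampling gives the same answer.

`reader_group_ttest()` compares two professional groups (six radiologists
vs five radiographers in the motivating design) on per-reader FOMs (the
unweighted mean over all cells, appropriate for a balanced design) with
Welch's unequal-variance t-test.

## Mark scoring

`classify_marks()` converts raw (x, y, rating) marks into LL/NL using
Euclidean pixel distance and an acceptance radius, 20 px by default to
match the motivating study's capture rule. Choices where the capture rule
is silent, all deterministic:

* distance exactly equal to the radius counts as within (inclusive
  boundary);
* a mark within radius of several lesions goes to the nearest; exact
  distance ties break toward the lowest lesion id;
* when several marks hit the same lesion in one cell, the lesion's LL
  rating is the highest of them. The lower-rated surplus marks are
  **discarded** by default — a deliberate click-and-rate interface produces
  one perception event per perceived lesion, and demoting repeats to NL
  would double-count those events. `surplus = "demote"` is available for
  sensitivity analysis.

## The simulator

`simulate_froc()` generates scored datasets from a simplified search
model: per case and cell, NL marks arrive as Poisson(`nl_rate`) with
N(0, 1) ratings; each lesion is marked with probability `hit_prob` and
rated N(`mu`, 1), `mu` being the cell's detectability; a N(0, `reader_sd`)
reader effect shifts all of a reader's ratings. Defaults emulate the
motivating study's conditions: the 4 x 2 x 11 x (34 + 34) design, 1-3
lesions per abnormal case in the 23:10:1 mix of the phantom fixture,
`nl_rate = 1`, `hit_prob = 0.8`, `reader_sd = 0.3`, and a detectability
trend over factor 1 (`mu` from 1.8 to 3.0) with none over factor 2 —
parameters chosen once to put wAFROC FOMs in the mid-0.8s, where the study
observed them, with a visible exposure effect and a null reconstruction
effect. Ratings are continuous by default; `rating = "integer"` bins them
onto the 1-10 scale with fixed equal-width cut points on $[-2, 6]$
(data-independent, hence deterministic and order-preserving).

Randomness is split into substreams per (cell, reader, case), all derived
from one seed, so the same seed always reproduces the dataset exactly and
adding readers or cases does not perturb the other dimensions' draws.

What the simulator deliberately does **not** model: case-specific
difficulty (so cross-reader covariances $Cov_2, Cov_3$ are near zero and
random-case analyses are exercised only structurally), within-case
correlation between NL count and lesion conspicuity, satisfaction-of-search
effects, and any image or pixel content. Passing tests therefore validate
the *statistical machinery* under a clean generating model, not the
behaviour of human observers on real images.

`null_rejection_rate()` estimates the family-wise type-I error of the full
crossed procedure under a global null (identical `mu` everywhere — enforced,
since a non-null configuration would silently invalidate the estimate). The
validation suite uses a 2 x 2 factorial with 4 readers and 20 + 20 cases at
`mu = 1.0` over 1000 replicates, a size chosen to give a Monte-Carlo SE of
about 0.007 on the rate while the whole run stays in the minutes range;
the observed rate sits at the nominal 0.05 within two Monte-Carlo SEs.

## The phantom truth fixture

`make_phantom_truth()` rebuilds the study's case structure as a synthetic
truth table: 34 normal + 34 abnormal cases and 46 nodules whose
(level x depth x side) census matches the phantom's nodule distribution
cell for cell — 25:21 right:left, 8:26:12 upper:mid:lower, 8:25:13
anterior:posterior:central — with diameters from {5, 8, 10, 12} mm and
densities from {+100, -630, -800} HU. The per-case allocation 23 x 1,
10 x 2, 1 x 3 is the unique assignment of 46 nodules to 34 cases with
counts in {1, 2, 3} whose mean and SD round to the reported 1.35 ± 0.54.
The published census lists 18 peripheral nodules with per-(level, side)
counts that request five peripheral nodules in the lower-left cell, which
holds only four; the fixture keeps the main grid and the peripheral total
(and per-side peripheral totals) exact and reassigns the one surplus flag
to the mid-left cell, which has the largest spare capacity. Coordinates are
drawn inside 512 x 512 pixel boxes consistent with each nodule's side and
depth label; they are synthetic stand-ins (the real positions are not
published) sufficient for exercising radius-based scoring.

## Physics metrics

`cnr()` implements the standard single-background-ROI definition
$|\mu_{nodule} - \mu_{background}|/\sigma_{background}$ — contrast over
noise, with contrast reported separately, since reconstruction should move
the noise and not the HU values. `cnr_trend()` fits ordinary least squares
of CNR on mAs (continuous) and reconstruction (indicator).
`effective_dose()` computes the ICRP 103 tissue-weighted sum
$E = \sum_T w_T H_T$ with photon radiation weighting 1; the 13 remainder
tissues pool by their mean under the single 0.12 remainder weight, and the
weight table ships as data a user can replace. Dose is exactly linear in
exposure, which the tests assert as $E(cD) = cE(D)$.

## Numerical and degenerate-input choices

* A treatment-by-reader interaction mean square below machine tolerance
  raises an error rather than reporting $p = 0$; it occurs only in toy or
  duplicated data and infinities would corrupt the protected-rule logic.
* Deleting a case that would empty the normal or abnormal set is an error
  (the leave-one-out FOM is undefined), so jackknifing needs at least two
  cases of each kind.
* Designs must be complete; missing (factor1, factor2, reader) cells are
  an error, never imputed, because the ORH mean-square formulas assume
  balance. A reader with zero marks in a cell is indistinguishable in a
  CSV from a missing cell, so file-level completeness is checked as "every
  cell of the declared design appears at least once"; programmatic
  constructors (the simulator) bypass the check since their designs are
  complete by construction.
* The 1-10 integer scale is a validation default, not a hard limit; rating
  bounds are configurable so continuous simulator ratings flow through the
  same pipeline.

## Validation problem sizes

The shipped test suite checks the FOM implementations against brute-force
pair-enumeration oracles on 1000 random small datasets ($K_1, K_2 \le 5$,
up to 3 lesions per case), the $F = t^2$ identity on 1000 random 2 x J
tables, the jackknife against explicit deleted-case recomputation, the
type-I error bound on the 1000-replicate null described above, and every
count of the phantom census. These sizes were picked to make Monte-Carlo
conclusions sharp while keeping a full run of the suite in the minutes
range on a single CPU.

## Known limitations

* Fixed-reader random-case (FRRC) analysis, sample-size planning and
  equivalence testing are out of scope; failing to reject equality of two
  conditions is *not* evidence of equivalence.
* The simulator's clean generating model understates the covariance
  structure of real reader data (see above).
* Only two crossed factors are supported; the Bonferroni split
  generalises (`n_analyses`) but the analysis surface does not.
* Curve plotting is limited to FOM summaries and difference CIs; no
  FROC/AFROC curve fitting is provided.
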