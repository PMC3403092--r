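---
title: "LPFS: jointly selecting biomarkers and validating the classifier with one linear program"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LPFS: jointly selecting biomarkers and validating the classifier with one linear program}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LPFS)
```

## The problem

Binned ^1^H NMR profiling of plasma produces a few hundred intensity
features (0.01-ppm chemical-shift bins) per sample, with group sizes of ten
or so per arm. Biomarker discovery in this regime asks for a *small* subset
of bins that discriminates treated from control samples, because a short
marker panel is what can be assayed cheaply and interpreted biologically.
Ranking filters (t statistic, fold change) score features one at a time and
need an arbitrary cutoff; wrappers such as SVM-RFE rank by repeated
refitting. LPFS instead poses the subset itself as the optimization
variable and solves for it globally.

## The model

Samples are classified by the nearest-centroid rule under the L1 metric: a
sample goes to the class whose mean profile (restricted to the selected
features) is closer in the city-block sense. For a case sample $s$ with
case/control centroids $\mu^T, \mu^F$, correct classification restricted to
a 0/1 selection vector $x$ means

$$\sum_i |s_i - \mu^T_i|\, x_i \;<\; \sum_i |s_i - \mu^F_i|\, x_i ,$$

and symmetrically for controls. Writing the per-feature *distance gap*
$g_i = |s_i - \mu^F_i| - |s_i - \mu^T_i|$ (sign flipped for control
samples), every such constraint becomes $g \cdot x \ge \text{margin}$. A
nonnegative *tolerable error* $y_l$ per validated sample absorbs
violations, and the two goals — few features, few errors — are scalarized
by a trade-off $\lambda > 0$:

$$\min_{x, y} \; \sum_i x_i + \lambda \sum_l y_l
\quad\text{s.t.}\quad g_l \cdot x + y_l \ge \delta,\;\; 0 \le x \le 1,\;\; y \ge 0 .$$

Crucially, the validation structure is *embedded*: with leave-one-out
validation (the default) constraint $l$ uses fold centroids in which the
held-out sample is removed from its own group's mean, so the program
"sees" $m_1 + m_2$ genuine held-out classification events rather than
resubstitution fits. The resubstitution variant (full-group centroids,
optimistic by information leak) is retained for comparison.

The integer program is relaxed to a linear program over $0 \le x_i \le 1$;
the fractional optimum $x_i$ is the LPFS score of feature $i$ and its
strictly positive support (score $> 10^{-8}$) is the selected set.

## Numerical choices

**Margin.** The classification rule's strict inequalities cannot enter an
LP; without a positive margin, $x = 0, y = 0$ would be feasible and
trivially optimal. We therefore require $g_l \cdot x + y_l \ge \delta$
with $\delta > 0$. The margin is mandatory, not cosmetic.

**Row normalization.** Each gap row is divided by its mean absolute entry
(default on; a row of exact zeros — a sample that no feature separates
from the opposite centroid — is an error naming the sample). This makes
$\delta = 1$ natural and $\lambda$ scale-free, so a single default grid of
25 log-spaced values in $[10^{-2}, 10^3]$ spans the empty-selection regime
to the fully separable regime on any dataset, and a global intensity
rescaling provably leaves the solved problem, hence the selection,
unchanged. Raw-coefficient mode (`rowNormalize = FALSE`) is kept for
oracle tests.

**Score bound.** The relaxation keeps the box $x_i \le 1$ inherited from
the binary formulation by default, so scores read as fractional
selections; `xUpper = Inf` gives the unbounded-score variant.

**Solver.** The LP is solved by a dense bounded-variable primal simplex
written for this constraint structure: the system $[G\; I]$ contains an
identity on the error variables, so $x = 0, y = \delta$ is a feasible
basis and no phase-1 is needed. Dantzig pricing with a Bland's-rule
fallback guards against cycling, ratio-test ties break on the smallest row
index (deterministic vertices), and tolerances are $10^{-9}$ on reduced
costs. Problems here are tiny by LP standards (20 rows, a few hundred
columns; about a millisecond per solve), and the implementation is
cross-checked in the test suite against an independent LP solver
(`pracma::linprog`) and against an exhaustive integer oracle that
enumerates all $2^n$ selections with the closed-form optimal errors
$y_l = \max(0, \delta - g_l \cdot x)$.

**Choosing $\lambda$.** Every grid point is solved and each selected set
is re-evaluated with a plain leave-one-out nearest-centroid run restricted
to it (`posthocLooAccuracy()`, the headline accuracy — binary re-use of the
set, independent of the LP's error variables). The chosen $\lambda$
maximizes this post-hoc accuracy, with ties broken by fewest selected
features and then by smallest $\lambda$. Empty selections have no
classifier and never win over a non-empty one. The error-variable accuracy
(`accuracyFromErrors()`, share of constraints with $y_l \le 10^{-6}\delta$)
is also reported but is internal to the optimization.

**Ties in classification.** A sample exactly equidistant from both
centroids is assigned to control — the null class, the conservative call
for a biomarker claim — with a warning.

## The synthetic generator

No reference dataset accompanies the method at desk scale, so the package
ships a seeded generator that emulates the study design it targets: 400
bins, 10 case vs 10 control samples, baseline intensities
$b_i \sim U(50, 150)$ and per-feature noise $\sigma_i \sim U(2, 10)$
(coefficients of variation of roughly 2–20%, typical of binned plasma
spectra), strictly nonnegative values (zero-truncated Gaussian; a
lognormal mode exists for realism checks), and a small planted subset
whose case mean is shifted by `shift` $\times\,\sigma_i$. Expressing
shifts in units of each feature's own noise keeps effect sizes analytic,
which is what the property tests need. What the generator does *not*
emulate: NMR peak shapes, chemical-shift correlation between bins of one
metabolite, batch drift. Passing tests on this generator therefore
demonstrate the optimization's behavior, not robustness to those real-data
phenomena.

The problem sizes used throughout the tests and the acceptance study —
50 random oracle instances with at most 8 features, 20 generator seeds for
the recovery and null studies at the full 400-bin scale, 100 random
matrices for the statistic cross-checks — were chosen as the smallest
designs at which each property is informative.

## What the method does and does not recover

Two behaviors of the model are worth stating plainly, because both follow
from its design and both are visible in the package's own acceptance
outputs.

*Minimal sufficient subsets, not the full planted set.* The objective
minimizes the feature count and the $\lambda$ choice rule prefers the
smallest set at equal accuracy. When several planted markers are each
individually sufficient to separate the groups (as at shift $4\sigma$),
the program returns one or two of them — a minimal perfectly separating
subset — rather than all. In the acceptance study the selected set is
essentially always a *subset* of the planted set (mean precision 1.0) with
perfect post-hoc leave-one-out accuracy, while exact support recovery is
rare. LPFS answers "what is the smallest panel that classifies?", not
"which features carry any signal?"; use the filter statistics for the
latter.

*Overfitting on null data at large $\lambda$.* With 400 features and only
20 embedded validation constraints, a linear program can interpolate pure
noise: at the large-$\lambda$ end the optimum drives all $y_l$ to zero on
exchangeable groups by combining a dozen or so noise features, and the
in-sample post-hoc accuracy of that set is high. The accuracy-maximizing
choice rule therefore does *not* return an empty selection on null data.
The meaningful null control is the permuted-label evaluation: reassigning
group labels at random brings the selected set's leave-one-out accuracy to
chance (about 0.5 in the acceptance outputs). Any selection produced on
real data should be accompanied by that permutation check, and by the
sham-experiment filter (`controlFilter()`) where a no-treatment control
arm exists.

## Baselines and evaluation utilities

The comparison methods mirror common practice: the two-sample t statistic
in its signal-to-noise form (mean difference over pooled sd, without the
$\sqrt{1/m_1 + 1/m_2}$ factor — the printed-formula convention, with
p-values treating it as approximately t-distributed), the raw-scale fold
change, the absolute log-fold-change ranking with a cutoff, and linear
SVM-RFE (squared-weight elimination criterion, regularization constant 1,
recorded). Sparse multinomial logistic regression is *not* reimplemented;
external selections can be imported as CSV/JSON and compared through the
same `SelectionResult` container. Evaluation helpers produce volcano-style
tables (mean difference vs pooled sd), Venn region counts for up to four
selections (pairwise Jaccard beyond that), the sham-experiment set
difference, and precision/recall against a known planted truth (empty
selections score precision 0 with a flag rather than NaN).

## Preprocessing contract

The intended pipeline order for binned spectra is: exclude the residual
water window (closed interval, 4.6–5.1 ppm by default; exclusion must
precede normalization or the excluded bins still contribute to each
sample's total), constant-sum normalize each sample (default total 1, so
profiles read as fractions; the convention fixes no particular constant),
then optionally log-transform (base 2 by convention) and Pareto-scale
(center, divide by the square root of the sd; the variance of a scaled
column equals the original column's sd, and constant columns map to zero).
Sample standard deviations use the $n-1$ denominator throughout — material
at $n = 10$. Raw spectral processing (phasing, Fourier transform, baseline
correction, peak identification) is upstream of this package, which
consumes already-binned tables.

## A worked run

```{r worked}
sim <- syntheticProfiles(nFeatures = 400, m1 = 10, m2 = 10,
                         planted = c(86, 87, 92, 308), shift = 4, seed = 7)
path <- lambdaPath(sim$dataset)
path
selectedFeatures(path)
recoveryMetrics(selectedFeatures(path),
                featureIds(sim$dataset)[sim$truth$planted])[c("precision",
                                                              "recall")]
```

The chosen selection is a minimal separating subset of the planted bins,
with post-hoc leave-one-out accuracy 1 — the behavior discussed above.

## Limitations

Beyond the two recovery caveats: the model is linear in the per-feature
distance gaps, so interactions between features enter only through the
shared centroids; group sizes below about five per arm leave the embedded
leave-one-out structure with too few constraints to be informative; the
exhaustive integer oracle is limited to 20 features by construction; and
multi-class designs and n-fold validation variants are out of scope for
this version.
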