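---
title: "Parenclitic networks from methylation profiles: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parenclitic networks from methylation profiles: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parenclitic)
```

## The model

A parenclitic network is a per-subject graph over a fixed gene panel.  A
*control group* of healthy samples defines, for every unordered gene pair
$(i, j)$, a reference model of how the two methylation levels co-vary in
health.  For any other subject with levels $(x_i, x_j)$, the edge weight
between genes $i$ and $j$ measures that subject's deviation from the
reference:

* **Regression kernel.**  Ordinary least squares on the controls gives
  $m_j = \alpha_{ij} + \beta_{ij} m_i$ with residual standard deviation
  $\sigma_{ij}$, and the weight is
  $w_{ij} = |x_j - (\alpha_{ij} + \beta_{ij} x_i)| / \sigma_{ij}$ — the
  residual in control-sigma units.
* **Mahalanobis kernel.**  With control mean $\mu_{ij}$ (a 2-vector) and
  $2\times2$ covariance $S_{ij}$, the weight is the *squared* Mahalanobis
  distance $w_{ij} = (x - \mu_{ij})^\top S_{ij}^{-1} (x - \mu_{ij})$.  The
  squared form is the kernel's definition here; a square-root variant is
  available (`squared = FALSE`) but off by default.

The regression kernel only sees displacement *off* the regression line.  A
disease cluster displaced *along* the line leaves residuals untouched for
that pair, while the Mahalanobis kernel still measures the separation —
this is the motivation for the second kernel, and in practice it buys a
small but consistent accuracy margin (about one percentage point on the
synthetic study below; the effect is small precisely because the graph is
complete, so a marginal shift of one gene is still caught by its edges to
every unshifted gene through the regression kernel too).

Healthy subjects produce homogeneous networks with modest weights;
diseased subjects produce networks whose most abnormal genes become heavy
hubs.  Twelve topology indices summarize each network and feed a
classifier.

## Conventions adopted where the formulation is open

Several details are not fixed by the method's description; the package
adopts the following and stamps them into outputs:

* **Regression orientation.**  The pair is unordered in the graph, but the
  regression is not symmetric.  The predictor is always the
  lower-indexed gene of the pair (recorded in the model).
* **Estimator divisors.**  Residual standard deviation and covariances use
  the unbiased $n-1$ divisor.
* **Degenerate pairs.**  A constant predictor or an exactly linear control
  relation makes $\sigma_{ij} = 0$ (regression) or $S_{ij}$ singular
  (Mahalanobis).  Singular covariances receive a ridge (default $10^{-8}$)
  on the diagonal; zero-sigma regression pairs are flagged and dropped
  from the edge set with a warning, because the kernel is undefined there.
  `strict = TRUE` turns their presence into an error.
* **Rescaling.**  Gene-level aggregation averages probe values and, if the
  result leaves $[0, 1]$, applies a *global* min–max rescale (per-gene
  rescaling is available but destroys between-gene level differences).
  Rescaling happens after averaging; for in-range data the two orders
  coincide.  The applied mode is recorded in the `rescale` attribute.
* **k-NN imputation.**  Distance between probe rows is the RMS difference
  over mutually observed samples; the imputed value is the unweighted mean
  of the $k$ nearest rows' values at that sample.  Detection-flagged
  values still participate in distances (only true missing values are
  excluded), which keeps the procedure defined even when every entry is
  flagged.  Unflagged missing values are imputed by the same rule so that
  downstream stages always receive a dense matrix.

## Path-length semantics

Distances are defined as the minimal *sum of edge weights* along a path,
and all path-based indices (mean/variance of shortest paths, diameter,
efficiency, betweenness) use the weights directly as lengths.  This is the
literal reading of the definition, but note its consequence: abnormal
(heavy) edges are *long*, so increasing abnormality tends to increase the
diameter.  The opposite intuition — strong abnormal connections acting as
short cuts — corresponds to `edge_to_length = "inverse"`
(length $= 1/w$), which is equally supported and stamped into every output;
the two modes answer different questions and are not interchangeable.
Classification results are insensitive to the choice on the synthetic
cohorts because the classifier sees a monotone transform of the same
contrasts.

Numerical guards: path-length ties are resolved with a relative tolerance
of $10^{-9}$ when counting shortest paths (weighted betweenness is
ill-posed without one); distances below $10^{-12}$ contribute the capped
value $10^{12}$ to efficiency (this arises only for samples essentially
identical to the control mean); zero-weight ties in path counting are
broken by node index.

## The 12 topology indices

In fixed order: mean, sample variance and maximum of edge weights; mean,
variance and maximum of weighted node degrees ($\deg(v) = \sum_u w_{vu}$);
mean and variance of shortest-path lengths over unordered pairs; diameter;
degree centralization; efficiency; and mean per-node betweenness.
"Variation" is read as sample variance, not the coefficient of variation.
Betweenness is defined per node; the single index is its mean over nodes.

Degree centralization follows the printed normalization
$C_D(G) = \sum_i |C_D(v^*) - C_D(v_i)| / ((|V|-1)(|V|-2))$ with
$C_D(v) = \deg(v)/|V|$ on weighted degrees.  Two consequences are worth
stating plainly: a unit-weight star on $n$ nodes scores $1/n$ (not 1),
and uniform weight scaling by $c$ scales the score by $c$ — the index is
*not* scale-free, unlike betweenness.  Both follow directly from the
formula and are covered by tests.

## Classification protocol

The two-step cross-validation separates control-group selection from
classifier evaluation:

1. The healthy pool is shuffled (seeded) and split into 2 folds (fewer
   than 50 healthy samples) or 4 folds (otherwise).  Each fold in turn is
   the control group, used *only* to fit the pairwise models; the held-out
   healthy samples join the classification set as negatives alongside all
   disease samples.
2. On the classification set, stratified 10-fold cross-validation
   evaluates a random forest (500 trees) or an RBF support-vector machine
   on standardized features.  Stratification is mandatory because held-out
   healthy samples are scarce.

Confusion counts are pooled over inner and outer folds — folds have
unequal sizes, so pooling counts is better defined than averaging rates;
note that each disease sample is classified once per outer fold, so pooled
counts weight disease samples by the fold count.  Specificity is the
fraction of healthy samples classified negative, sensitivity the fraction
of disease samples classified positive.  AUC is deliberately not a default
output: with one or two healthy samples per inner fold it is rarely
defined.  Classifier hyperparameters are deliberately plain (the method is
claimed, and observed, to be insensitive to the classifier choice); all
are configurable and echoed in the result object.

## Degree distributions

`degree_ccdf()` uses the strict tail definition
$P(\deg > x)$.  Group curves are averaged pointwise on a shared
log-spaced grid (pooling degrees first is available as `mode = "pooled"`).
`fit_power_law()` defaults to transparent least squares on the log–log
CCDF; the reported `exponent` is the tail exponent $a$ in
$P(\deg > x) \sim x^{-a}$ and `alpha` $= a + 1$ the corresponding density
exponent.  A continuous maximum-likelihood mode (`method = "mle"`) is
available when raw degrees are retained; it is the better estimator for
raw samples with a genuinely continuous tail, but it is biased on heavily
discretized data at small `x_min`.  Power-law behaviour is a *tail*
property: when comparing groups, fit above a tail threshold (for example
the degree where the CCDF first drops below one half) rather than over
the whole support — over the full range the smooth bulk of the healthy
curves and the plateau-and-cliff shape of hub-dominated disease curves can
produce deceptively similar whole-range $R^2$ values.  The
healthy-versus-disease comparison is reported as the difference in
goodness of fit, a tool output rather than a built-in verdict.

## What the synthetic generator does and does not emulate

`generate_cohort()` draws linked gene pairs from a correlated bivariate
normal on the logit scale and squashes through the logistic function, so
values are beta-like and bounded without clipping artefacts.  Disease
samples are displaced on the linked pairs either off the regression line
(`off_line`, in control-residual sigmas, random sign per sample) or along
it (`along_line`, in marginal sigmas, a coherent cluster shift), or a
mixture.  Controls and healthy test samples are exchangeable draws from
the same distribution, and identical specs are byte-reproducible.

Default sizes are the package's reference study: 50 genes, 60 controls,
60 healthy test samples, 120 disease samples, pair correlation 0.7, half
of the possible disjoint pairs linked, latent noise 0.5 on the logit
scale, and an off-line displacement of 5 residual sigmas.  At these
settings the two-step cross-validation recovers the disease signal nearly
perfectly, and with displacement zero it sits at chance — both are checked
by the test suite at exactly these sizes, which keep the full suite within
a few minutes on one CPU.

Two honest caveats.  First, the logistic squash is nonlinear, so an
along-line displacement on the logit scale leaks slightly into beta-scale
regression residuals (a disease/healthy residual ratio around 2 rather
than exactly 1); the contrast between kernels, which is the point of that
geometry, is unaffected.  Second, real 450k data have probe-chemistry
artefacts, batch effects, spatial correlation along the genome and
cohort-level confounders that the generator does not emulate; passing
tests demonstrate correctness of the machinery, not expected accuracy on
real cohorts.

## Known limitations

* Dense pairwise storage is quadratic in the panel: comfortable to a few
  thousand genes, and the 15k-gene scale of full methylation panels needs
  a blocked out-of-core pass that this version does not implement.
* The degree-centralization index inherits the printed normalization's
  scale dependence (see above); comparisons across kernels or length
  modes should use features from one convention.
* `fit_power_law()` reports descriptive goodness (log–log $R^2$, KS
  distance); it performs no likelihood-ratio model comparison against
  alternatives such as log-normal tails.
* The preprocessing stage expects a caller-supplied probe blacklist; no
  platform annotation is bundled.
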