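---
title: "Methods: multi-voting similarity-ensemble target prediction and kinome panel analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-voting similarity-ensemble target prediction and kinome panel analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seavote)
options(seavote.quiet = TRUE)
```

## The problem and the model

A multi-component preparation — a fixed set of known small molecules — acts
on many proteins at once, mostly weakly. The pipeline in this package
triangulates its *direct* kinase targets from three mutually independent
lines of evidence: chemical-similarity prediction, database annotation, and
kinome-panel inhibition data.

### Similarity-ensemble statistics

The prediction stage is a similarity ensemble approach (SEA). A target is
represented by its set of annotated ligands; a query compound (a singleton
set) is compared to each target's set under a binary fingerprint. The raw
score between fingerprint sets $A$ and $B$ is

$$RS(A,B) \;=\; \sum_{a \in A}\sum_{b \in B} Tc(a,b)\,\mathbf{1}[Tc(a,b)\ge t],
\qquad Tc(a,b) = \frac{|a\cap b|}{|a\cup b|},$$

with Tanimoto threshold $t = 0.57$ by default (the canonical SEA choice;
configurable per fingerprint kind). Raw scores grow with set sizes, so they
are standardized against a randomized null: ligand-set pairs of prescribed
sizes are drawn at random from the pooled reference ligands, and the null
mean and standard deviation are fitted by ordinary least squares as linear
functions of the set-size product $n = |A|\cdot|B|$:

$$\mu(n) = \alpha_1 n + \alpha_0, \qquad \sigma(n) = \beta_1 n + \beta_0 .$$

The default calibration grid is $\{(2,2),(4,4),(8,8),(16,16),(32,32)\}$ with
100 pairs per cell; the seed, grid, per-cell statistics and fit residuals
are stored in the model, and an identical seed reproduces identical
coefficients exactly. The model refuses to extrapolate beyond $10\times$ the
largest calibrated $n$ — beyond that the linear fits are unsupported and the
right response is recalibration, not silent extrapolation. A calibration in
which every sampled raw score is zero (threshold too high for the pool) or
in which the fitted $\sigma(n)$ is non-positive anywhere on the calibrated
range (pool too homogeneous, e.g. identical fingerprints) aborts with a
diagnostic rather than producing an unusable null.

The standardized score $z = (RS - \mu(n))/\sigma(n)$ is converted to a tail
probability under a Gumbel-type extreme-value null,

$$P(z) = 1 - \exp\!\big(-x\big), \qquad x = e^{-z\pi/\sqrt{6} - \gamma},$$

with $\gamma$ the Euler–Mascheroni constant, and reported as an E-value
$E = P \cdot N$ over the $N$ targets of the searched reference
(single-library correction; the constant is configurable). Numerically,
$1-\exp(-x)$ is evaluated as `-expm1(-x)`, and for $x < 10^{-8}$ by the
series $x - x^2/2 + x^3/6$, so the tail is accurate to better than twelve
significant digits across $z \in [-10, 20]$; in double precision $P$
saturates at exactly 1 for $z \lesssim -4.5$, which is why monotonicity is
strict only below the saturation region. Ranked output is ordered by
ascending E-value with ties broken by descending best pairwise Tanimoto and
then lexicographic target id, making outputs byte-stable under any
reference ordering.

### Five models, one vote

Five fingerprint types — path-based topological (max path 7, 2048 bits),
Morgan radius 2 (2048 bits), the 166 MACCS keys, hashed atom pairs
(2048 bits) and 2-point topological pharmacophore pairs (folded to
2048 bits) — give five independently calibrated SEA models. No published
parameterization exists for the ensemble this design follows, so community
defaults are used and every parameter is exposed. A pair
(compound, target) is *predicted* when at least `vote_threshold` models
flag it at their per-model E-value cutoff. The default threshold is 3, a
strict majority of 5; threshold 1 reproduces the union of the models and
threshold 5 their intersection, and the predicted set is anti-monotone in
the threshold by construction.

**Per-model E-value cutoff.** The cutoff default deserves a note, because
it was the one genuinely open calibration in this design. A fixed "small"
cutoff such as $10^{-5}$ is only meaningful relative to the reference
geometry: against a 20-target reference with 10-ligand sets (the default
synthetic world), a *perfect* chemotype match attains $z \approx 8$–$9$ and
hence $E \approx 10^{-4}$, so a $10^{-5}$ cutoff would reject every true
association a flawless search can produce. The package therefore defaults
to $E \le 0.05$ — fewer than 0.05 false targets expected per search under
the null — the standard significance convention on the E scale. The
measured separation in the default synthetic world is $\sim 2\times10^{-4}$
for planted pairs against $\sim 12$ for null pairs, three orders of
magnitude on either side of the cutoff, so the default is structural, not
tuned.

### Kinome restriction and integration

The kinome stage's contract is simply "a predicted-kinase set per
compound". It is satisfied either by loading an external predictor's export
(identifiers are validated against a shipped kinase vocabulary; unknown
symbols are logged and dropped) or by a deterministic similarity surrogate:
kinase $K$ is predicted for a compound iff the maximum Tanimoto similarity
between the compound and $K$'s reference ligands reaches a cutoff (default
0.57). The external deep model that inspired this stage is deliberately
*not* reimplemented — the pipeline treats it as an oracle, and the
surrogate keeps the stage exercisable offline. Filtering is a per-compound
set intersection: idempotent, never additive.

Known (database-annotated) and predicted targets are merged by gene symbol
— with an optional user-supplied two-column mapping table replacing
proprietary annotation services — into records with provenance `known`,
`predicted` or `common`. Counts follow the inclusive convention of
published intersection tables: the known and predicted counts each include
the common subset, so total = known + predicted − common. Validation
accuracies (100 × active/tested per provenance class) are rounded half-up
to one decimal, matching how such tables are conventionally printed; a
class with zero tested targets reports an undefined accuracy, never 0.

### Panel screening

Residual activity is the treated sample's kinase activity as a percentage
of the untreated blank (blank = 100); lower means stronger inhibition.
Classical single-compound conventions call < 30 strong and 30–70 moderate
inhibition; for a multi-component preparation, whose single components
contribute weak superposed interactions, the screen uses a *more permissive*
threshold of 80. Two boundary decisions are fixed by the shipped worked
example: the active call is **inclusive** (activity ≤ 80; the printed panel
contains two kinases at exactly 80 among its actives, which forces
inclusivity), and the retest selection is **strict** (activity < 70; no
printed kinase sits exactly at 70, so strictness is a convention and is
recorded in the run configuration).

Dose dependence between the screening and retest concentrations is flagged
when inhibition deepens by at least `margin` percentage points:
$a_{high} \le a_{low} - m$, with a strict decrease additionally required so
that a zero margin flags exactly the strict decreases. The default
$m = 10$ reproduces all nine flags of the shipped retest table while
leaving the four rebounding kinases (whose inhibition *weakened* at the
higher dose) unflagged. The source table's high-dose value for one kinase
(CLK1) is typographically ambiguous and is stored as missing — its flag
propagates as `NA`, never as a guess — which is also why no flat rule can
be declared "the" published criterion and the margin remains configurable.

### Dose–response fitting

IC50s are estimated from dilution series (default 10 points, 3-fold) with
the four-parameter logistic

$$y(c) = bottom + \frac{top - bottom}{1 + (c/IC_{50})^{h}},$$

fitted by bounded nonlinear least squares (L-BFGS-B with analytic
gradients) on log-concentration, parameterized in $\log IC_{50}$ so the fit
is exactly scale-equivariant. Bounds on the percent scale — bottom in
[−10, 50], top in [50, 120], Hill slope in [0.1, 10], IC50 within
[min c/100, max c×100] — keep the fit in the physically meaningful regime;
initialization takes the observed extremes and the concentration nearest
the midpoint response. Each replicate is fitted independently and the
report is the mean ± sample SD (n−1) of the per-replicate IC50s, the only
reading consistent with commercial mean-±-SD kinase reports; SD is defined
as 0 for a single replicate. A series whose response range is below
`flat_tol` (default 10 points) yields an *undefined* IC50 with an explicit
flag, and non-convergence is likewise flagged, never silent. A stalled
line search at machine precision still counts as converged when the
bound-projected gradient is negligible.

## The synthetic world

The generator plants ground truth that the pipeline must recover. In the
default abstract-fingerprint mode each target owns a disjoint *core* block
of fingerprint bits shared by all its ligands; each ligand adds private
bits drawn from a common background region. With $m$ bits per ligand, an
expected pairwise intersection $i$ gives $Tc = i/(2m-i)$, so core size,
private count and background size are solved in closed form from the
requested within-target and between-target similarities. Defaults — 20
targets, 10 ligands per target, within-Tc 0.7, between-Tc 0.05, 64 bits in
a 2048-bit space, 3 planted query compounds per target — are the stated
benchmark world of this package's acceptance checks; the realized
similarities land within ±0.01 of the design values at seed 7. Edge cases
are exact: chemotype similarity 1 yields identical ligands, background
similarity 0 allocates globally unique private bits so cross-target
Tanimoto is exactly zero.

Panels are generated as Gaussian draws around an active mean (default 50)
and an inactive mean (default 95) with SD 5, truncated at zero — a
separation chosen so the 80% screen sits 6 SD from both populations, which
is what a well-designed screen looks like and what makes ≥ 28/30 recovery a
fair regression bar rather than a coin flip. Dose–response curves are the
4PL plus Gaussian noise (default SD 3 points, 3 replicates), with the
generating parameters recorded for recovery tests.

What the generator does *not* emulate: real chemotypes are not random bit
blocks (they share scaffold substructure, not arbitrary features), real
reference sets have heterogeneous sizes and inter-target correlation, panel
noise is not Gaussian at the 0 floor, and real assay replicates share
plate-level systematics. A green synthetic run therefore establishes that
the statistics, voting, filtering and fitting machinery are correct — not
that any particular biological prediction is.

All generators are pure functions of their seed (Mersenne-Twister with
fixed normal/sample kinds), so every output is byte-reproducible across
platforms.

## Numerical and design choices

* **Tanimoto of two empty fingerprints is 0**, not NaN, so degenerate
  structures can never create spurious perfect matches. Empty fingerprints
  are an error for the substructure kinds, but are legitimate — and
  flagged — for MACCS on degenerate structures *and* for the 2-point
  pharmacophore on molecules with fewer than two pharmacophoric features
  (benzene has none under the Gobbi feature definitions); the latter
  carve-out was verified against the reference implementation.
* **Chemistry is delegated**, not reimplemented: SMILES validation,
  canonicalization and all five fingerprint kinds run in RDKit through a
  small packaged Python bridge. The bit-set containers, Tanimoto kernel and
  every statistic above them are pure R, so the entire synthetic pipeline
  runs without the bridge.
* **Background fits are unweighted OLS** on per-cell means and SDs; the
  per-cell statistics and residuals are retained in the serialized model so
  a reviewer can judge fit quality.
* **The raw score is exact**: the sparse-matrix path is tested for exact
  equality (not tolerance) against a brute-force double loop, with the
  summation order pinned so the comparison is legitimate in floating point.
* **Worked-example arithmetic is frozen**: partition totals
  (479/148/109), accuracies (40.5/29.2/55/28.3) and the 30/14/9 screening
  cascade are recomputed from the shipped printed tables by the same code
  paths used for synthetic data.
* **Configuration is a single validated tree**; unknown keys are rejected,
  contradictory thresholds (retest cutoff above the active threshold) are
  refused, NULL-valued keys are dropped so validation is idempotent, and
  the full configuration plus derived seeds is serialized into every run
  manifest, from which a run is exactly reconstructible.

## Known limitations

* The five-model ensemble treats models as exchangeable voters; no weights
  are learned and no cross-model probability calibration is attempted.
* The linear $\sigma(n)$ null is the conventional SEA form, but on small
  pools the large-cell SD is inflated by chemotype clustering, which makes
  E-values conservative (true matches look *less* significant than under a
  clustering-aware null).
* The similarity surrogate for the kinome stage is a deliberately simple
  stand-in; its predictions agree with an exhaustive max-similarity scan by
  construction but carry none of the external deep model's learned
  generalization.
* Dose–response fitting assumes independent replicates and homoscedastic
  noise; pooled-replicate fitting and robust loss are out of scope.
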