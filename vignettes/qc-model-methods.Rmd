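---
title: "Quadratic convolutional models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quadratic convolutional models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the numerical procedures, and the
design decisions behind `qconv` — in particular the choices that the
method itself leaves open and that a user should know before trusting a
fit.

## The model

The QC model predicts a spike count $Y_t$ from a grayscale stimulus movie
through three nonlinear stages.  Patches $x_{k,t}$ (one per grid position
and latency) are passed through *identical* quadratic logistic subunits

$$y_{k,t} = \sigma\!\left(a^{(1)} + v^{(1)}\cdot x_{k,t} +
  x_{k,t}^\top J\, x_{k,t}\right),$$

pooled with signed weights $v^{(2)}$ and rectified,

$$r_t = R_+\!\left(d \sum_k v^{(2)}_k y_{k,t} + a^{(2)}\right),
\qquad R_+(x) = \log(1+e^x),$$

and the parameters $(a^{(1)}, v^{(1)}, J, v^{(2)}, a^{(2)}, d)$ minimize
the Poisson negative log-likelihood $\sum_t (r_t - Y_t \log r_t)$.  A
saturating output variant $r_t = d\,\sigma(\cdot + a^{(2)})$ is available
through `model_spec(final_nonlinearity = "logistic")`.  Reduced variants
remove the quadratic kernel (`quadratic = FALSE`, linear models) or
collapse the grid to one centered patch per latency
(`convolutional = FALSE`).

Conventions, fixed throughout: pixels are indexed 0-based and row-major;
a patch is labelled by its top-left corner; lag $\ell$ means the patch
from frame $t-\ell$ (response depends on present and past frames only);
the pooling axis is ordered lag-major (lag slowest, grid positions
row-major within a lag); frames without a full lag history are dropped
from the likelihood rather than zero-padded.  The grid is anchored at
offset 0, so 16×16 patches at stride 1 in a 20×20 frame give the full
5×5 grid of offsets 0–4 per axis.  Movies are mean-centered on load and
*not* variance-normalized — the biases absorb offsets, and leaving the
scale alone keeps $J$ interpretable in stimulus units.

The subunit stage has an exact sign symmetry
($a^{(1)}, v^{(1)}, J, v^{(2)} \to$ their negatives, with the output bias
shifted by the pooled constant).  Fitted folds are mapped to the
orientation with $\sum_k v^{(2)}_k \ge 0$ before averaging, so fold
averages cannot cancel and "excitatory" (positive-eigenvalue) features
are features that increase the rate.

## Fitting

Plain minibatch SGD with classical momentum on the mean-per-frame NLL.
The optimizer hyperparameters are deliberately exposed rather than tuned
away (`fit_config`): learning rate (default 0.02 — conservative for
quadratic kernels; linear fits tolerate 0.1–0.2), batch size (500),
momentum (0.9), and a small-Gaussian initialization (sd $10^{-3}$) of
$v^{(1)}, J, v^{(2)}$ with the output bias set so that the initial rate
equals the mean count.  This near-linear start keeps the subunits away
from saturation.  Because the subunit weights and the pooling weights
multiply each other, the first epochs climb out of a saddle; with very
small data sets or few epochs the fit can stall at the constant-rate
solution, which is why patience values of 4–8 are the package default
territory rather than 1–2.

The data are split into four *contiguous* temporal fourths (movies are
temporally correlated; shuffled splits would leak training frames into
validation).  Each fourth serves once as the early-stopping validation
set: validation NLL is evaluated every epoch, the best-validation
parameters are kept, and training stops after `patience` non-improving
epochs.  The four fold models are averaged element-wise.  Given
`fit_config(seed = )`, fits are bit-reproducible.

Model evaluation on repeated trials reports the Pearson correlation
between prediction and trial-averaged response divided by an estimated
ceiling: split-half reliability (interleaved odd/even trials), inverted
through Spearman–Brown to a single-trial reliability $\rho_1$, then
extrapolated to the $n$-trial mean,
$\mathrm{ceiling} = \sqrt{n\rho_1/(1+(n-1)\rho_1)}$.  The corrected value
is clipped to $[0, 1]$; a zero-variance prediction returns 0 with a
warning.

## Eigen-feature significance

`significant_features` subtracts the grand mean of $J$ (a nonzero mean
produces one spurious extreme eigenvalue), then builds null distributions
of the largest and smallest eigenvalues from matrices whose diagonal
entries are permuted among diagonal slots and upper-triangle entries
among off-diagonal slots (mirrored for symmetry).  Eigenvalues are tested
in order of decreasing magnitude — positive against the max-null,
negative against the min-null — and testing **stops at the first
non-significant eigenvalue**.  No deflation is applied after a
significant component is found; the method description does not call for
any, and the sequential stop already prevents isolated late false
positives.  The default 1000 shuffles resolve $p = 0.05$ with a standard
error of about 0.007.

Two properties of this test are worth knowing.  First, the first tested
eigenvalue is the larger in magnitude of (max, min), each compared to its
own tail at $\alpha$; under a pure-noise kernel the family-wise rate of
declaring at least one feature therefore lies between $\alpha$ and
$2\alpha$, not at $\alpha$ — the calibration test asserts exactly that
band.  Second, the shuffle null conserves the entry multiset of $J$, so
strong real structure inflates the null's extreme eigenvalues; weak
components riding on strong ones are conservatively discarded.

## Gabor decomposition by differential evolution

The excitatory and suppressive parts of $J$ (rebuilt from the significant
eigencomponents of each sign) are separately approximated as
$\sum_i w_i g_i g_i^\top$ with unit-norm Gabor images

$$g(x,y) \propto \exp\!\left(-\frac{x'^2 + \gamma^2 y'^2}{2\sigma^2}\right)
  \cos\!\left(\frac{2\pi x'}{\lambda} + \phi\right),$$

$x', y'$ the coordinates rotated by $\theta$ about $(x_0, y_0)$.
The optimizer is the rand/2/bin differential evolution variant: population
$10P$ ($P$ = free parameters), mutant
$u' = u_{r_1} + F(u_{r_2}-u_{r_3}) + F(u_{r_4}-u_{r_5})$ with five
distinct partners excluding the target, binomial crossover with one
forced coordinate, and per-member $CR \sim \mathrm{rand}[0,1)$,
$F \sim 0.1 + 0.9\,\mathrm{rand}[0,1)$ re-drawn with probability
$\tau = 0.1$ before mutation and retained only when the trial wins
(jDE).  $\sigma, \gamma, \lambda$ are searched in log space; positions
are bounded by the frame, angles by $(-\pi, \pi]$; out-of-bounds trials
score infinite error; replacement is greedy on MSE; a run ends when no
member changes in an iteration (with a `max_iter` safety cap, default
500, because the strict rule alone is unbounded), and the best of
`restarts` independent runs is kept.  Restarts are the method's remedy
for premature population collapse — single-Gabor self-recovery typically
needs 3–6 of them to reach a normalized MSE below 0.02.

Two design choices are ours.  The weights $w_i$ are not part of the DE
genotype: at every objective evaluation they are solved exactly by
sign-constrained least squares on the $n\times n$ Gram system
($A_{ij} = (g_i\cdot g_j)^2$, $b_i = g_i^\top J g_i$), nonnegative for
excitatory fits and nonpositive for suppressive ones.  This halves the
search dimension and makes the MSE landscape depend only on Gabor
geometry.  In quadrature mode each pair shares all parameters with phases
fixed at 0 and $\pi/2$, and its two members carry independent
(sign-constrained) weights; the energy-model kernel of a quadrature pair
is invariant to the pair's common base phase, which is why the fixed
phases cost nothing.

Pairing and phase: Gabors with center distance below one mean wavelength
and axial orientation difference below 30° qualify as pair candidates;
greedy nearest-neighbour matching accepts candidates in order of combined
dissimilarity, ties broken toward larger total $|w|$.  The phase
difference is corrected for the displacement along the carrier,
$\Delta\phi = \mathrm{wrap}(\phi_a - \phi_b - \tfrac{2\pi}{\bar\lambda}
\Delta x \cdot \hat n)$, with $\bar\lambda$ the harmonic mean wavelength
("mean spatial frequency" acts on frequency, not wavelength) and
$\hat n$ the unit carrier direction at the pair's axial mean orientation.
Because $(\theta + \pi, \phi)$ and $(\theta, -\phi)$ describe the same
Gabor, both members are first expressed with carriers in the same
half-plane; without this the phase of axially-equal Gabors is compared in
opposite frames.  Results are reported in $[0°, 180°)$.

## Population metrics

*Sparseness.*  The method's source never defines "sparseness"; we adopt
the Treves–Rolls / Vinje–Gallant lifetime form
$S = (1 - \bar r^2/\overline{r^2})/(1 - 1/n)$, the standard in this
literature, and record it in output metadata.  "Without suppressive
features" means rebuilding $J$ from the significant excitatory
eigencomponents only, all other parameters fixed — mirroring the
eigen-decomposition that defines the features, rather than zeroing Gabor
weights.  Sparseness comparisons are computed on held-out stimuli.

*Orientation spread.*  Orientations are axial (mod 180°) everywhere.  The
spread is the circular angular deviation on doubled angles,
$\sqrt{2(1-R)}$, halved back to orientation units; the alternative
$\sqrt{-2\log R}$ diverges for orthogonal orientation sets and cannot
express their finite maximal spread.  Populations are split into
"uniform"/"nonuniform" classes at a supplied threshold or at the largest
gap of the empirical spread distribution.

*Pooling decomposition.*  $v^{(2)}$ reshaped to (grid × lags) is
factorized by rank-1 SVD, sign convention: temporal peak positive.  A map
is "biphasic" when its positive and negative lobes each carry more than
20% of the total absolute mass — this threshold is ours, exposed as
`lobe_frac`, since no criterion is stated by the method.

*Dip statistic.*  Implemented from scratch (no suitable dependency): the
dip is located by bisection on the tube half-width $d$, using the fact
that a unimodal CDF within $d$ of the empirical CDF exists iff, for some
peak segment, the lower convex hull of the box tops clears the box
bottoms on the left and mirror-wise on the right.  Tied observations are
separated by an infinitesimal jitter, which is exactly the limit that
allows a unimodal CDF to carry an atom at its mode.  The implementation
agrees to $5\times 10^{-13}$ with an exact linear-programming formulation
(the independent oracle used in the tests) on hundreds of random samples.
P-values are Monte-Carlo ranks against uniform null samples of the same
size (cached per size within a session).

*Orientation-difference histograms* use 8 equal bins over $[0°, 90°]$ and
a $\chi^2$ statistic with 7 degrees of freedom against uniformity.

## Synthetic ground truth, and what passing tests show

`generate_stimulus` produces white Gaussian movies or per-frame Fourier
synthesis with a $1/f$ amplitude spectrum and random phases, standardized
to zero mean and unit variance.  This reproduces the second-order
statistics of natural movies but none of their higher-order structure
(no phase alignments, no contrast fluctuations, no temporal
correlation across frames).  Ground-truth neurons are built from known
Gabor quadrature pairs (`qc_ground_truth`: excitatory pair, optional
orthogonal suppressive pair, uniform or biphasic pooling) or from a
third-order interaction among three orthonormalized Gabor features
(`third_order_neuron`): the response is the soft-plus-rectified,
gain-scaled triple product of the feature projections plus a baseline —
the rectifier is our choice, as the source does not print the output
nonlinearity, and rates must be valid Poisson means.  Every ground-truth
rule is also evaluated by a deliberately naive straight-loop
implementation with no shared code with the vectorized model path; the
test suite requires both to agree to $10^{-12}$.

Recovery tests at synthesis scale therefore demonstrate that the
estimator and its optimizer work — not that real cortical data are this
benign.  In particular, the third-order recovery (subspace projection of
the true features onto the significant eigenvectors ≥ 0.6 at $10^5$
frames, 12×12 patches) exercises the regime where the quadratic model
detects purely higher-order structure through its even part; on natural
stimuli, correlations between orders make this easier, so the synthetic
bound is close to worst-case.  The cross-orientation sparseness
directions hold for suppressive weights up to about half the excitatory
weight — physiologically, cross-orientation suppression attenuates rather
than silences — and reverse for suppression strong enough to veto the
excitatory drive entirely; the fixture uses weights 3 (excitatory) and
1.5 (suppressive).

## Problem sizes used by the tests

Recovery and comparison tests run at reduced, fixed scales chosen once:
third-order recovery at $10^5$ frames × 12×12 non-convolutional;
the end-to-end complex-cell pipeline and model-ladder comparison share
one fit at 3×10⁴ frames of 12×12 movies with 10×10 patches, stride 2 and
2 lags; eigen-test calibration uses 200 replicate 20×20 kernels with 500
shuffles; DE self-recovery uses 12×12 patches.  The published-scale
geometry (20×20×10 movies, 16×16 patches, 250 pooling weights) is
available through the same configuration objects.

## Known limitations

* Plain SGD with a fixed learning rate is the only optimizer; very large
  kernels ($P \gtrsim 400$) fit slowly and may need learning-rate tuning.
* The shuffle null conserves total kernel energy, so feature counts are
  conservative when a few components dominate.
* The dip p-value is Monte-Carlo, not interpolated from published tables;
  at the default 500 null draws its resolution is ±0.002 near 0.05.
* No adapter for external electrophysiology archives is included:
  datasets enter through the package's own serialized container
  (`write_dataset`/`read_dataset`).
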