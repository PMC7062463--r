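---
title: "Estimating nonlinear receptive-field subunits by spike-triggered clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating nonlinear receptive-field subunits by spike-triggered clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stclust)
```

## The model

Many sensory neurons — retinal ganglion cells (RGCs) most prominently —
pool *rectified* inputs from presynaptic units rather than summing the
stimulus linearly. `stclust` models binned spiking responses with a
two-stage linear–nonlinear (LNLN) cascade: the stimulus frame
$X_t \in \mathbb{R}^D$ is filtered by $N$ subunit kernels $K_n$, each
passed through an exponential, and the weighted sum drives a saturating
output nonlinearity and a Poisson spike generator,

$$
\lambda_t = g\!\Big(\sum_{n=1}^{N} w_n \, e^{K_n \cdot X_t}\Big),
\qquad
g(x) = \frac{x^{a}}{1 + b x}, \quad a > 0,\ b \ge 0,
\qquad
Y_t \sim \mathrm{Poisson}(\lambda_t).
$$

Rates are expected spike counts per stimulus bin; the bin width is
absorbed into the weights $w_n$. The printed form of $g$ admits two
readings; we adopt $x^a/(1+bx)$ because it nests the identity at
$a=1, b=0$ — the regime fitted nonlinearities end up near — and exposes
saturation through a single parameter $b$ (the alternative $ax/(1+bx)$ is
the special case $a=1$ up to scale).

## The estimator

Maximum-likelihood estimation proceeds in two stages.

**Stage one** estimates $\{K_n, w_n\}$ ignoring $g$. For stimuli with
approximately standard-Gaussian statistics (which temporally prefiltered,
per-pixel standardized binary white noise satisfies), the mean-rate term
of the Poisson negative log-likelihood is replaced by its analytic
expectation via the Gaussian moment generating function,
$\mathbb{E}[e^{K \cdot X}] = e^{K \cdot K / 2}$, giving the *approximate*
objective

$$
\mathcal{L} = \sum_n w_n e^{K_n \cdot K_n / 2}
            - \frac{1}{T} \sum_{t: Y_t > 0} Y_t \log \sum_n w_n e^{K_n \cdot X_t},
$$

which depends on the data only through the spike-triggered stimuli.
Minimizing a convex majorizer of $\mathcal{L}$ (first-order Taylor
expansion of the data term around the current parameters) yields a soft
clustering of spike-triggered stimuli, iterating three closed-form
updates:

1. responsibilities
   $\alpha_{t,n} \propto w_n e^{K_n \cdot X_t}$ (softmax over subunits);
2. filters
   $K_n \leftarrow \sum_t Y_t \alpha_{t,n} X_t \big/ \sum_t Y_t \alpha_{t,n}$
   (responsibility-weighted centroids), optionally followed by a
   proximal regularization step;
3. weights
   $w_n \leftarrow \big(\tfrac{1}{T}\sum_t Y_t \alpha_{t,n}\big) e^{-K_n \cdot K_n/2}$.

Each sweep decreases $\mathcal{L}$ monotonically. At an unregularized
fixed point the strength-weighted filter sum
$\sum_n (w_n e^{K_n \cdot K_n / 2}) K_n$ is proportional to the
spike-triggered average, so the method is a strict generalization of STA
estimation ($N = 1$ reproduces the STA exactly);
`sta_decomposition_residual()` verifies this identity on fitted banks.
The *strength* $w_n e^{K_n\cdot K_n/2}$ — a subunit's average
contribution to the firing rate — is the canonical ordering and display
weight throughout the package, and the strengths of a converged bank sum
to the mean spike count per bin.

**Stage two** (`fit_output_nonlinearity()`) holds the filter directions
fixed and fits $a$, $b$ and per-subunit weight scales by minimizing the
exact Poisson negative log-likelihood with BFGS (analytic gradients;
positivity by log/softplus reparameterization; three deterministic
starts, best kept, skipping the third when the first two agree to
$10^{-8}$).

### Numerical choices

* **Initialization.** Filters start at the STA direction plus i.i.d.
  Gaussian noise with sd $0.1\,\|\mathrm{STA}\|/\sqrt{D}$, weights at
  (mean rate)/$N$. The symmetric start lies near a saddle: every subunit
  initially claims the same stimuli. During the escape the surrogate
  changes per iteration are tiny but *growing*, so convergence is
  declared only when the relative change falls below `tol` ($10^{-6}$)
  **and** is no longer increasing; stopping on the small-change criterion
  alone would freeze fits at the saddle after two sweeps. The iteration
  cap is 100, the regime in which these fits typically converge.
* **Empty clusters.** A subunit whose responsibility mass underflows is
  reseeded from a random spike-triggered frame (counted in `rescues`).
* **Counts, not binarized spikes.** Bins with $Y_t > 1$ enter all
  updates with multiplicity $Y_t$.
* **Weight update scale.** The responsibility mass is divided by the
  total bin count $T$; this is what makes the stationarity identity
  "strengths sum to the mean rate" hold and is required for dimensional
  consistency of the surrogate.

## Regularization

With limited data relative to the stimulus dimension, unregularized
filters go noisy. Two proximal penalties plug into the centroid step:

* **L1** — elementwise soft threshold at $\lambda$; sparsity, but
  indifferent to *where* pixels sit.
* **Locally normalized L1 (LNL1)** — penalty
  $\sum_i |k_i| / (\epsilon + \sum_{j \in \mathrm{nbr}(i)} |k_j|)$ with
  $\epsilon = 0.01$ (small against typical order-one filter values).
  Each clustering iteration takes one majorize–minimize step: the penalty
  is linearized at the incoming filter, giving per-pixel thresholds
  $a_i \lambda$ with $a_i = 1/(\epsilon + \sum_{\mathrm{nbr}} |k_j|)$.
  Isolated pixels face thresholds up to $\lambda/\epsilon$ and are
  suppressed; pixels with strong neighbors are barely shrunk. The penalty
  is *not* permutation-invariant — a contiguous blob is strictly cheaper
  than any pixel shuffle of it — which is exactly the prior wanted for
  compact subunits, with little pressure on their overall size.

Neighborhoods are 4-connected grid adjacency (diagonals excluded, borders
truncated; 8-connectivity is a switch). The pixel itself is excluded so
a pixel cannot license itself. Regularization applies per subunit; the
surrogate separates across subunits, so the prox is applied to each
centroid independently. $\lambda$ is chosen on validation likelihood.

## Hierarchical and population variants

`fit_path()` grows a model one subunit at a time. A split replaces parent
$m$ by two children at $K_m + \varepsilon_i$ (noise sd
$0.05\|K_m\|/\sqrt D$; no magnitude is canonical, this keeps children
within a few percent of the parent) with half the parent weight each.
Children are refined with *factorized* responsibilities
$\alpha_{m_1} = \alpha_m \sigma$, $\alpha_{m_2} = \alpha_m(1 - \sigma)$,
$\sigma$ a two-way softmax with biases $\log w$ — mass is conserved
exactly at every split — while all other subunits stay frozen, which
makes evaluating every candidate parent cheap. The split with the largest
surrogate gain is kept; by default (`refine = "joint"`) the accepted
configuration is then polished by full joint updates, which is what makes
each level agree with the flat fit of the same size to within about a
percent of held-out likelihood ("frozen" skips the polish and is faster
but stays a warm-started approximation).

`fit_population()` clusters the pooled spike-triggered stimuli of several
cells: responsibilities are per cell, the shared filters pool
responsibility-weighted frames across cells (each cell's frames weighted
by its own spike counts — the per-cell counts belong in the shared
centroid just as they do in the single-cell update), and weights are per
cell, with $w_{n,c} = 0$ meaning "not connected". With one cell the code
path is literally the single-cell engine, so results are bit-identical
given the same seed. Subunits contributing under 1% of a cell's total
strength are flagged (not removed) as poorly estimated for display.
LNL1 is the default prior here because the shared stimulus window is the
union of the cells' receptive fields and therefore high-dimensional.

## Null stimuli

To expose subunit nonlinearity experimentally, white noise is projected
frame-by-frame onto the null space of the fitted spatial receptive
fields: $S_n = (I - A(A^\top A)^{-1}A^\top) S_w$, the *closest* such
stimulus in L2. Any model that begins by linearly integrating over space
with a filter in the span of $A$ — every LN model — responds to $S_n$
with a constant rate, while subunit cascades keep responding.

Two display constraints are then enforced with Dykstra-style cyclic
projections: the pixel range (box $[-0.5, 0.5]$, projected last so
output frames always respect it) and the per-pixel temporal variance
(each mean-removed pixel trace rescaled to the target — a sphere, hence
non-convex; Dykstra's convergence guarantee covers convex sets only, so
convergence is monitored via per-constraint residuals and reported, never
assumed). Starting the white noise at 48% contrast leaves the box
constraint slack, and the cycle converges in tens of iterations. The
variance is enforced about each pixel's mean. Frames are finally
quantized to 8-bit display levels (round-half-even), and the
post-quantization orthogonality residual is reported rather than
asserted.

Full spatio-temporal nulling (`spectral_null()`) transforms each pixel
trace to the temporal frequency domain, projects the complex spatial
vector at every frequency onto the orthogonal complement of the filters'
content there, and transforms back (conjugate symmetry preserved, so the
result is real). The implementation nulls every discrete frequency under
a circular boundary convention; for a space–time separable filter this
reproduces spatial nulling to machine precision, which is also the
package's regression check of the separability argument.

## The ground-truth simulator

`rgc_cell()` builds the validation workhorse: 64 cones on a hexagonal
lattice (5 g.u. spacing, rotated 60° to the pixel grid, positional jitter
sd 0.35 g.u.; 1 g.u. ≈ 1 µm), pooled spatially with a Gaussian (sd 1
g.u., integrated exactly over pixel areas) and a shared biphasic temporal
kernel (difference of gammas, peak ≈ 50 ms, trough ≈ 80 ms, unit norm —
a generic parasol-like time course; the exact shape is configurable and
nothing downstream depends on it). k-means on cone positions (20
restarts) partitions them into 12 bipolar pools; each bipolar
exponentiates its summed cone drive; bipolar weights are positive
normals with 10% coefficient of variation around one. Because the weight
mean and the bipolar input scale are not separately identified, the
weight mean is fixed at 1, the input gain defaults to 1.5 — chosen once
so bipolar log-drives have standard deviation of order one under default
48% binary noise — and a single global output gain is calibrated so the
mean rate on a calibration run hits the 19 spikes/s target; fresh draws
then land within a few percent. The stimulus grid extends three pixels
beyond the mosaic so that background pixels dominate robust noise
estimates in receptive-field masking.

The exported `true_subunits` are exactly the bipolar pooling maps on the
pixel grid, so the simulated cell *is* an LNLN model with exponential
subunits — recovery tests compare estimated filters against this truth
(after mapping truth into the standardized stimulus coordinates). With
coarse pixels several cones fall into one pixel and neighboring bipolars
blur together; cross-validated fits then select fewer subunits than the
12 bipolars, the expected aggregation behavior, not an estimator failure.

`toy_cell()` provides the low-dimensional counterparts: three unit-norm
filters at distinct angles in a 2-D Gaussian stimulus space (the
geometry used throughout the recovery and hierarchy tests) and five
compact Gaussian blobs on an 8×8 pixel grid (the stability fixture).

**What the simulators do not emulate:** photoreceptor adaptation and
cone noise, spike-history/refractory structure, recording noise and
spike-sorting errors, inter-cell noise correlations, and natural-image
statistics. Passing recovery tests therefore demonstrates correctness of
the estimator under its own model class and Poisson variability — not
robustness to every failure mode of physiological data.

## Preprocessing, partitioning, selection

The spike-triggered average (lags zero-padded at the recording start)
is factorized by SVD into space × time; the receptive field is the
largest 4-connected component of pixels exceeding 2.5 robust standard
deviations (MAD × 1.4826 over all pixels — the field is mostly
background by construction), cropped with a one-pixel border. The time
course averages the traces of significant pixels after aligning each
trace's sign by its own peak (so ON- and OFF-polarity pixels reinforce
rather than cancel; restricting to center-sign pixels is the plausible
alternative and differs only in the surround). The raw movie is then
convolved with the time course per pixel and standardized per column —
no cross-pixel whitening, since binary noise is pixelwise independent.

Data are partitioned with the test set as the contiguous tail (10%) and
random train/validation splits of the rest. `select_model()` averages
validation likelihood over repeated splits and fresh initializations for
every $(N, \lambda)$ and then applies the **one-standard-error rule**:
the most parsimonious setting (smallest $N$, then largest $\lambda$)
within one standard error of the best mean. Plain argmax is unstable
here because an $(N{+}1)$-subunit model nests every $N$-subunit model
and ties with it to within validation noise on clean simulated data; the
1-SE rule is the standard cross-validation remedy and recovers the
generating $N$ reliably.

Prediction accuracy on repeated trials is the Pearson correlation
between the data PSTH and the PSTH of the same number of simulated
Poisson trials from the model. PSTHs use Gaussian smoothing (sd 16.67
ms, truncated at 4σ with edge renormalization so kernel mass — hence
total count — is conserved). Response structure is the temporal variance
of the PSTH; subunit geometry is quantified by 2-D Gaussian fits to
max-normalized filters (MSE as the locality score, with a pixelwise
permutation control whose null quantiles are uniform), and tiling by
nearest-neighbor center distances normalized by the geometric mean of
the two fits' standard deviations along the joining direction.

## Problem sizes used in the checks

The automated checks run the toy cells at $1.5\times10^4$–$2\times10^5$
frames (recovery and selection use $2\times10^5$), the coarse-pixel
simulator at 1.5–8 simulated minutes, and the regularization comparison
at 3 simulated minutes of 96% contrast fine-pixel (4 g.u.) noise —
duration and resolution chosen so that unregularized fits are genuinely
data-limited, which is the regime the spatial priors address; at coarse
resolution or long duration the unregularized estimator is already
accurate and all three variants coincide. The population comparison uses
two three-subunit cells sharing one subunit at $6\times10^4$ frames.

## Known limitations

* The Gaussian-expectation objective is exact only for (approximately)
  standard-normal stimuli; for strongly non-Gaussian ensembles (natural
  scenes) filters must be estimated from white noise and only the output
  stage refit, as the package's two-stage API encourages.
* Subunits share one temporal filter (space–time separability). The
  estimator runs on any frame parameterization — space × time bins for
  flickering-bar stimuli work unchanged — but non-separable retinal
  subunits are out of scope.
* The clustering objective is non-convex; different seeds can reach
  different local minima. Multi-restart selection and the hierarchical
  path mitigate but do not eliminate this.
* Dykstra cycles with the variance sphere have no convergence theorem;
  residuals are reported so a failed construction is visible.
* Greedy subunit matching between banks is not globally optimal; the
  test suite pins an adversarial case documenting the behavior.
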