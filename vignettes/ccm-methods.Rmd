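---
title: "Convergent cross mapping with ccmtools: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convergent cross mapping with ccmtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmtools)
```

## The method

Convergent cross mapping (CCM) asks a deceptively simple question: can the
historical record of a putative *effect* reconstruct the states of its
putative *cause*? If variable X drives variable Y, then Y's trajectory
carries an imprint of X. Takens' theorem makes this operational: the cloud
of lagged coordinate vectors

$$\big(Y(t),\, Y(t-\tau),\, \dots,\, Y(t-(E-1)\tau)\big)$$

— the *shadow manifold* $M_Y$ — is, generically, a diffeomorphic image of
the attractor of the full dynamical system that Y belongs to. Points close
on $M_Y$ correspond to close system states, hence to similar values of
every variable coupled into that system, including X. Cross-mapping
exploits this: to predict a held-out $X(t-\tau_p)$ we find the $E+1$
nearest neighbours of $M_Y$'s point at time $t$ inside a *library* of L
consecutive manifold points (the held-out target itself excluded), convert
their distances $d_1 \le \dots \le d_{E+1}$ into simplex-projection
weights

$$u_i = \exp(-d_i / d_1), \qquad w_i = u_i \Big/ \sum_j u_j,$$

and form $\hat X(t-\tau_p) = \sum_i w_i\, X(t_i - \tau_p)$. Predictive
skill $\rho_{\mathrm{ccm}}$ is the Pearson correlation between held-out
observations and their cross-mapped predictions.

The causal criterion is not the size of $\rho_{\mathrm{ccm}}$ but its
*convergence*: as the library grows, the manifold fills in, neighbours
become genuinely close, and — if and only if the mapped variable is
dynamically coupled — skill rises systematically with L. A static
correlation without coupling produces a flat curve. Directionality follows
from the asymmetry of the construction: `y xmap x` (predicting X from
$M_Y$) tests "X causes Y", a convention every label in this package spells
out in full because it is the single most common point of confusion.

## Skill estimation: sliding windows

For a library size L we slide a window of L consecutive manifold points
with stride 1, compute leave-one-out predictions for every valid target in
the window, and one Pearson $\rho$ per window; the per-L skill is the mean
over windows. Repetition over an increasing ladder of L values produces
the convergence curve. We chose window-averaging over pooling all windows'
predictions into a single correlation because short noisy series produce
window-to-window variation that the average summarises honestly; the
per-window values are retained in the output for inspection.

Edge rules, chosen so the optimizer never sees NaN:

* a target whose $\tau_p$-shifted index leaves the series is skipped and
  counted (never silently dropped); neighbours with invalid shifts are
  excluded from candidacy;
* windows with fewer than 3 usable pairs have undefined skill (NA) and are
  excluded from the mean;
* zero variance on either side of the correlation yields
  $\rho_{\mathrm{ccm}} = 0$ with a flag rather than NaN;
* neighbour ties are broken toward the earlier time index, making every
  computation deterministic;
* if the nearest neighbour distance is exactly zero, weights are uniform
  over the zero-distance neighbours;
* a Theiler exclusion window (default 0, i.e. only the target excluded) is
  available to guard against serial-correlation leakage.

## Tuning parameters

Two parameters are optimized, mirroring the method's practice:

* **E** — the embedding dimension. Its optimum $E^\*$ bounds the
  dimensionality of the underlying causal system via Whitney's theorem:
  generically between $\lceil (E^\*-1)/2 \rceil$ and $E^\*$, inclusive
  (`whitney_bounds()`).
* **$\tau_p$** — the assumed causal lag, in sampling steps. The manifold
  point at time t predicts the opposing series at $t-\tau_p$, so positive
  $\tau_p$ means the cause precedes the effect.

The coordinate lag $\tau$ between embedding coordinates is a separate
knob, default 1, and is deliberately *not* optimized.

Defaults for a series of length N (`default_grid()`): $E \in \{2, \dots,
\min(10, \lfloor\sqrt{N}\rfloor)\}$, $\tau_p \in \{0, \dots, \min(10,
\lfloor N/5 \rfloor)\}$, and for each E roughly eight library sizes spaced
evenly from $\max(E+2, 10)$ to the manifold size. The method wants at
least 25 observations; between 10 and 24 the package proceeds with a
warning, below 10 it refuses.

The objective for a cell (E, $\tau_p$) is the *maximum* over the library
ladder of the mean windowed skill — the plateau value of the convergence
curve — not the convergence increment; the sensitivity heatmaps show the
same quantity.

### Optimization: multi-start cyclic coordinate descent

(E, $\tau_p$) are tuned by cyclic coordinate descent: full line scans of
the E axis with $\tau_p$ fixed, then of the $\tau_p$ axis with E fixed,
repeated until a full cycle changes nothing (at most 10 cycles). Skill
landscapes over (E, $\tau_p$) are rough enough to trap a single descent in
axis-aligned local optima, so the descent is run from a small
deterministic set of starts — the four grid corners plus the centre — and
the best run wins. Cell evaluations are memoised and distance matrices are
computed once per E and shared across all $\tau_p$ and all library sizes,
so the extra starts cost little. Ties are broken toward smaller E, then
smaller $\tau_p$, preferring simpler embeddings. `full_surface()`
evaluates every cell exhaustively and is the audit path: the descent
optimum is checked against the exhaustive argmax in the test suite.
Infeasible cells (series too short for the embedding) are reported as
missing, never as zero.

## The convergence verdict

`assess_convergence()` reports $\Delta\rho = \rho(L_{\max}) -
\rho(L_{\min})$ and the relative difference $\Delta\rho /
\max(|\rho(L_{\max})|, 10^{-6})$, and a boolean verdict requiring both
$\Delta\rho \ge 0.1$ and $\rho(L_{\max}) \ge 0.2$. The underlying
criterion is qualitative — causal curves rise, non-causal curves lie flat
— so both thresholds are explicit, configurable defaults rather than
claims of optimality.

Strong external forcing is the method's principal failure mode: a third
variable driving both series can induce convergent cross-map signal
between non-interacting variables. The (E, $\tau_p$) sensitivity surface
is the built-in diagnostic; a result whose skill depends erratically on
the assumed dimensionality and lag deserves suspicion.

## Synthetic systems

Two generators provide ground truth for every pipeline stage; both take an
explicit seed and never consult hidden RNG state.

**Coupled logistic maps** (`coupled_logistic()`), the canonical CCM
benchmark:
$$X_{t+1} = X_t(r_x - r_x X_t - \beta_{yx} Y_t), \qquad
  Y_{t+1} = Y_t(r_y - r_y Y_t - \beta_{xy} X_t).$$
Defaults $r = 3.8$ (chaotic band), unidirectional forcing $\beta_{xy} =
0.32$, $\beta_{yx} = 0$, n = 400, burn-in 100 steps. Noise is
observational, added after the dynamics, so the true coupling stays
exact. Runs that escape (0, 1) are rejected and reseeded with a warning.
With these defaults the forced direction shows strong convergence
(typically $\rho$ rising from near 0 at L = 10 to about 0.9 at L = 399)
while the reverse direction stays flat — the direction-recovery behaviour
the acceptance tests quantify over 20 seeds.

**A predator-prey microcosm** (`predator_prey()`), emulating a ciliate
predator grazing a ciliate prey sampled every 12 h for 30 days (n = 60): a
discrete stochastic Ricker-type consumer-resource map with lognormal
process noise (environmental stochasticity), a small immigration floor
playing the role of the physical refuge that keeps laboratory microcosms
from collapsing, mild predator self-limitation, and lognormal observation
noise. Defaults produce a bounded quasi-cycle with a period of about 9
samples (4.5 days), roughly 7 cycles per 60-point series, both series
strictly positive. The grazing (top-down) coupling is parametrically the
stronger term.

What these fixtures do and do not show: they demonstrate that the pipeline
detects coupling, orients it under unidirectional forcing, refuses
convergence on independent noise, and loses power when a 60-point record
is thinned to 20 points (the quasi-cycle is then sampled ~2-3 times per
period and aliasing destroys the embedding). They do not reproduce every
feature of real microcosm data — in particular, the relative ordering of
the two directions' skill in the bidirectional fixture is delicate. Across
an extensive parameter search we found that in bounded stochastic regimes
the bottom-up mapping (embedding the predator) tends to achieve slightly
higher terminal skill at matched (E, $\tau_p$) even when the top-down
coupling is parametrically stronger; the mean convergence increment
$\Delta\rho$ favours the top-down test under the default conditions, but
not uniformly across seed sets. Real systems in which the top-down test
dominates decisively feature extreme boom-crash excursions that a bounded,
numerically well-behaved generator deliberately avoids. The test suite
therefore asserts the aggregate $\Delta\rho$ ordering under the frozen
default conditions, and readers should treat direction *comparison* (as
opposed to direction *detection*) on short bidirectional series as the
least robust output of the method.

## Numerical and engineering choices

* Distances are plain Euclidean on manifold points, computed once per
  (E, $\tau$) with `stats::dist` and reused across every library window
  and every $\tau_p$ — precomputation is what makes exhaustive surfaces
  affordable.
* The per-window sweep is implemented in C++ (Rcpp): for each window, a
  partial selection of the $E+1$ nearest candidates with the
  (distance, time) tie-break, the exponential weights including the
  zero-distance rule, and the per-window Pearson correlation. The test
  suite pins this fast path to a deliberately naive pure-R double-loop
  reference implementation at $10^{-10}$ tolerance, and `ccm_skill()`
  (used by the R path) delegates to `stats::cor`.
* Problem sizes in the test suite were chosen to exercise the method, not
  to stress hardware: oracle comparisons run at n ≤ 60, simulation
  properties at n = 60-400 over 20 seeds; a full suite run takes well
  under a minute on one core.
* Reading delimited input sniffs the separator, auto-detects a header row,
  and treats a leading arithmetic-progression column as a time axis (kept
  only as the sampling step; the algorithm works in index units).
  Columns are selected by name or 1-based position, the R convention.
* Missing or non-finite values are rejected at load. CCM needs complete,
  regularly sampled series; imputation is a modelling decision that
  belongs upstream, not a silent default.

## Known limitations

* Equal spacing is assumed, not enforced beyond the optional time column.
* Only pairwise analyses are provided; multivariate embeddings mixing
  several variables' lags are out of scope.
* No surrogate-data significance test is included; the convergence verdict
  is a heuristic with explicit thresholds, not a p-value.
* Bootstrap library resampling and S-map local linear forecasting are not
  implemented; sliding contiguous windows are the only library scheme.
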