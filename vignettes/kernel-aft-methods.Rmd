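---
title: "Censored kernel ridge regression for AFT models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censored kernel ridge regression for AFT models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kernaft)
```

# The model

For right-censored survival data $\{T_i, \delta_i, x_i\}_{i=1}^n$ with
$\delta_i = 1$ when the event was observed and $\delta_i = 0$ when follow-up
ended first, the accelerated failure time (AFT) model treats the natural log
of the survival time as a regression target:
$$M(x_i) = w^t\phi(x_i),$$
where a censored observation only constrains the fit from below
($M(x_i) > \log T_i$ when $\delta_i = 0$, since the true event time exceeds
the censoring time) while an event pins it ($M(x_i) \approx \log T_i$).

`kernaft` fits this model by ridge regression with a per-sample activity
indicator,
$$J(w) = \frac{1}{2n}\sum_i I_i\{w^t\phi(x_i) - \log T_i\}^2
       + \frac{\lambda}{2}\,w^t w,$$
where $I_i = 1$ for events, and for censored samples $I_i = 1$ exactly while
the current fit violates the lower bound ($M(x_i) \le \log T_i$). Setting the
gradient to zero shows $w = \Phi^t a$ with dual variables
$$a_i = -\frac{I_i}{n\lambda}\{K(x_i,\cdot)a - \log T_i\},$$
so the whole problem lives in the $n \times n$ kernel matrix
$K = \Phi\Phi^t$. This is what makes the method practical for gene
expression studies where $n$ is around $10^2$ and $m$ beyond $10^4$: no
computation ever touches an $m \times m$ object.

## The dual solver (DKRR)

`fit_dkrr()` runs Gauss–Seidel sweeps over the dual coordinates of the
centred system. One design point deserves emphasis. The fixed-point equation
above suggests the literal update
$a_i \leftarrow -I_i (K_i a - y_i)/(n\lambda)$, but as an *iteration* that
scheme diverges whenever the spectral radius of $K/(n\lambda)$ exceeds one —
which is the typical case here ($\|K\|$ grows with $n$ and useful penalties
are small). We therefore use the exact coordinate minimiser
$$a_i \leftarrow \frac{y_i - K_i a + K_{ii} a_i}{K_{ii} + n\lambda},$$
which has the *same* stationary points (the displayed fixed-point equation
holds at convergence) and, for uncensored data, is classical Gauss–Seidel on
the symmetric positive definite system $(K + n\lambda I)a = y$ — guaranteed
to converge to the unique kernel ridge solution from any start. The censoring
indicator is re-evaluated for each coordinate at the moment it is visited;
censored coordinates whose constraint is satisfied are clamped to zero, so at
convergence every censored sample fitted above its censoring time carries
$a_i = 0$.

Centring follows the usual double-centring identities: the training Gram
matrix is centred on both sides, test kernels are centred with the training
column means, and the training mean log-time serves as the intercept.
Predictions are always anchored to the *training* mean: centring the test
outcomes by their own mean would leak the test distribution into the
predictions, so we never do it outside of diagnostics.

### Kernels

Linear, polynomial $(x^ty + c)^d$ (offset $c = 1$ by default, the standard
inhomogeneous choice), sigmoid $\tanh(\beta x^ty)$, and Gaussian
$\exp(-|x-y|^2/\sigma^2)$ — note the denominator is $\sigma^2$, with no
factor 2. The rbf width defaults to the median pairwise distance of the
training rows, a scale-robust heuristic that needs no tuning; all Figure-type
kernel comparisons in the package use it.

## Sparse selection in the dual (AKRR)

With $n \ll m$ a linear kernel and an $L_p$ penalty ($p \le 1$) give
simultaneous selection and estimation:
$$J(w) = \frac{1}{2n}\sum_i I_i\{w^t x_i - \log T_i\}^2
       + \frac{\lambda}{2}\sum_j \frac{|w_j|^2}{|u_j|^{2-p}}, \qquad u = w.$$
Freezing the latent weights $u$ makes the penalty a weighted ridge, whose
dual lives on the adaptive kernel
$K_u = X\,\mathrm{diag}(|u|^{2-p})\,X^t$; the primal coefficients are
recovered explicitly as $w = X_u^t a$. `fit_akrr()` alternates
(i) $u \leftarrow w$ and a rebuild of $K_u$, (ii) a few censored Gauss–Seidel
sweeps on $a$, (iii) $w = X_u^t a$, until $\|w - u\|_\infty < \varepsilon$.
This is an iteratively-reweighted ridge of the FOCUSS family: coordinates
with small $|w_j|$ have their columns down-weighted by $|w_j|^{2-p}$ and decay
multiplicatively to zero, which is where the sparsity comes from. For $p = 1$
the objective is convex; for $p < 1$ only local optima are guaranteed, and
`fit_akrr_multistart()` scores random restarts on a holdout split (we default
to an inner holdout rather than the test set, to keep test outcomes out of
every selection decision).

### Tunable parameters and their defaults

* `lambda` — penalty weight, dimensionless, searched in $(0, 1]$. Cross-
  validated via `grid_search()`; the useful range shrinks with $p$.
* `p = 0.6` — the smallest exponent at which the iterates are empirically
  insensitive to initialisation; smaller values are sparser but multimodal.
* `inner_sweeps = 5` — dual sweeps per kernel rebuild. A single sweep (the
  minimal scheme) leaves the dual variables lagging the reweighting enough to
  make selection unstable — in our experiments single-sweep runs randomly
  dropped true variables that five sweeps retain — while five sweeps cost
  $O(n^2)$ each, negligible next to the $O(n^2 m_{\mathrm{active}})$ rebuild.
* `init = "ones"` — all features start with equal weight, so the first
  iteration is a plain ridge fit and the procedure is deterministic. Uniform
  random starts occasionally kill a true feature before the data can speak
  (its initial weight enters the kernel as $|u_j|^{2-p}$); we keep them
  available for multistart exploration at small $p$.
* `eta = 1/3` — relative sparsity threshold applied once after convergence:
  $w_j = 0$ where $|w_j| < \eta \max_j |w_j|$. At the penalties this model
  class favours, the converged coefficient profile is reliably bimodal:
  signal coefficients sit above roughly $0.4\,\max|w|$ and a handful of small
  noise-fitting coefficients below roughly $0.3\,\max|w|$ (the penalty is too
  weak to zero them exactly, because they absorb residual noise). The default
  sits in that gap; it is deliberately a *magnitude* threshold, since a signed
  threshold would delete every negative coefficient. The all-zero fit
  ($\lambda \ge \lambda_{\max}$) is recognised by comparing $\max|w|$ to the
  outcome scale.
* `u_floor = 1e-5` — initial weights are floored away from zero so no feature
  starts structurally excluded.
* `drop_tol = 1e-12` — columns whose adaptive weight falls below
  `drop_tol` $\times$ the largest are dropped from the Gram computation. The
  perturbation is below solver tolerance, and it is what collapses the cost of
  late iterations: a $m = 50{,}000$ fit spends a handful of dense iterations
  and then works on a few dozen active columns, finishing in seconds on one
  core.
* `eps = 1e-4`, `max_outer = 500` — outer convergence on
  $\|w - u\|_\infty$; non-convergence is reported in the `converged` flag,
  never as an error.

# The simulation generator

`make_dataset()` reproduces the censored-survival testbed used throughout
the package:

1. covariates are multivariate normal with AR(1) correlation
   $\Sigma_{ij} = r^{|i-j|}$, drawn by the exact recursion
   $x_j = r\,x_{j-1} + \sqrt{1-r^2}\,z_j$;
2. outcomes follow $\log T = s + w^t x^k + \varepsilon$,
   $\varepsilon \sim N(0, \sigma^2)$, with the componentwise power $k$
   producing nonlinear designs and the intercept $s$ chosen so the population
   mean log survival time equals `mean_log_time` (for even $k$ this removes
   the $E[x^k] = (k-1)!!$ contribution);
3. censoring times are $d_i = (U_i + C)\,T_i$ with $U_i \sim U(0,1)$, so
   events satisfy $\delta_i = 1\{T_i < d_i\}$ and the expected censoring
   fraction is $1 - C$ (the default $C = 0.5$ gives 50%, the midpoint of the
   40–60% range the studies target).

In the sparse high-dimensional layout (`sparse_w()`), twelve coefficients of
magnitude $\pm$`magnitude` sit at positions 1, 11, ..., 111; those twelve
features form one AR block among themselves and the remaining $m - 12$
features are independent $N(0, \sigma^2)$ noise (an `noise_ar` switch extends
the AR structure across all columns instead).

**Noise calibration.** The signal-to-noise ratio is interpreted per unit of
coefficient magnitude: $\sigma = \max_j|w_j| \cdot$
`mean_log_time`$/$`snr`. At the reference magnitude 1 with mean log time 3
and SNR 3:1 this is $\sigma = 1$; at magnitude 0.2 it is $\sigma = 0.2$, and
so on. The alternative — holding $\sigma = 1$ while shrinking the
coefficients — makes the weak-magnitude designs information-theoretically
unrecoverable (a coefficient of 0.1 against unit noise at $n_\mathrm{eff}
\approx 60$ censored samples has a standardised effect below 1, so *no*
estimator could select it reliably), which would contradict the selection
behaviour these designs are meant to exhibit; it is also the only reading
under which the cross-validated $\lambda^\ast$ values of the three magnitude
settings fall onto one scale-equivalence line
($\lambda^\ast \propto c^{2-p}$ for coefficients scaled by $c$). `sigma` can
always be set explicitly.

**Paired dimensions.** The signal block, the outcome noise and the censoring
draws use seed streams that do not depend on $m$, so two configurations
differing only in the number of noise features share their signal and
outcomes exactly. Comparisons across dimensions (the dimension-robustness
study) are therefore paired, and observed differences reflect the added noise
features rather than Monte Carlo noise.

**What the generator does not emulate.** Gaussian covariates and noise, a
single censoring mechanism proportional to the event time, exact sparsity,
and block-structured correlation are all idealisations: microarray data have
heavy-tailed, probe-level correlated expression, informative censoring is
possible, and true effects are neither exactly sparse nor equal-magnitude.
Passing the simulation studies shows the solvers implement the model
correctly and recover structure under the stated design — not that selections
on real cohorts carry the same error rates.

# Evaluation

`rrmse()` implements
$\sqrt{\tfrac1q \sum_i ((y_i - \hat y_i)/y_i)^2}$ on log survival times.
Two cautions are built in. Terms with $|y_i| < 10^{-8}$ are dropped with a
warning (the relative error is undefined at $y = 0$), and by convention the
package evaluates only test samples with an observed event — predicting a
censoring time accurately is not a meaningful target. Users should be aware
that on log-time outcomes whose distribution crosses zero this metric is
heavy-tailed: a handful of test samples with $|\log T|$ near zero can
dominate the mean, so replicate medians are reported alongside means in the
study summaries and large replicate counts are advisable.

`score_selection()` classifies a selected set against a known truth as
exactly matching, overfitting (all true variables plus extras) or
underfitting (at least one true variable missed); when a run both misses a
true variable and adds spurious ones it counts as underfitting, so the three
categories partition the replicates. `grid_search()` performs repeated
k-fold cross-validation over a $(\lambda, p)$ grid using training data only,
and tallies per-feature *relevance counts* — how many fold-fits selected
each feature, at most folds $\times$ repeats — the stability score used to
rank genes in two-fold/100-repeat designs.

# Problem sizes used by the packaged studies

The packaged reproduction studies run at desk scale, chosen to finish in
minutes on one core while keeping the Monte Carlo error of every reported
percentage below a few points: kernel comparisons use 20 replicates per
correlation in $r \in \{0.2, 0.4, 0.6, 0.8\}$ with 5-fold cross-validation
over five penalties; selection studies use $m = 1000$ and 100 replicates per
magnitude; the dimension study uses $m \in \{112, 1000, 10000\}$ with 20
paired replicates; the scaling check fits one $n = 100$, $m = 50{,}000$
problem.

# Known limitations

* **Selection at very high dimension.** With the twelve-coefficient design at
  $r = 0.4$, the two coefficients flanking the sign change carry a marginal
  signal of only $\approx 0.6$ of a standard unit after cancellation. By
  $m = 10^4$ that sits at the detection threshold
  $\sqrt{2\log m / n_\mathrm{eff}}$ for $n_\mathrm{eff} \approx 60$, and
  recovery of those two variables degrades no matter the penalty — a
  statistical limit of the design, not a solver artefact. The packaged
  dimension study reports this honestly rather than smoothing over it.
* **Multimodality.** For $p < 1$ distinct initialisations can reach different
  local optima; with $p \ge 0.6$ and the deterministic start this is rare but
  not impossible (an occasional extra proxy variable from a random start).
  The multistart wrapper exists for exactly this case.
* **Relative error on log times.** See the caution under *Evaluation*; when
  outcomes can approach $\log T = 0$, mean RRMSE across replicates has high
  variance and comparisons should rely on orderings and medians.
* **Ties and exact zeros.** Tied event times need no special handling (each
  tied sample contributes its own constraint); features with zero variance
  are never selected because their centred column is identically zero.
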