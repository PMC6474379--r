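---
title: "Saturating splines: model, algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saturating splines: model, algorithm, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A degree-one spline is a piecewise-linear continuous function
$f(x) = c + \sum_j w_j (x - t_j)_+$: a constant plus a finite combination
of hinge functions, one per knot $t_j$. Ordinary adaptive regression
splines choose the knots by penalizing the total variation of $f'$ — the
$\ell_1$ norm of the (distributional) second derivative — which yields
sparse, data-adaptive knot sets but leaves the fitted function growing
linearly beyond the data range, so extrapolation is unstable.

`satspline` adds *saturation*: the fitted function must extend as a
constant outside the (scaled) data interval $[0,1]$. Identifying the
second derivative of $f$ with a finitely supported signed measure
$\mu = \sum_j w_j \delta_{t_j}$, the fitting problem becomes a convex
program over measures,

$$
\min_{\mu,\,c}\; L(E_x\mu + c)
\quad\text{s.t.}\quad \|\mu\|_1 \le \tau,\;\; \textstyle\int d\mu = 0 ,
$$

where $L$ is a convex pointwise loss summed over observations,
$E_x\mu$ evaluates the hinge expansion at the data, $\|\mu\|_1 = \sum_j
|w_j|$ is the total variation of $f'$, and the zero-net-mass constraint
*is* the saturation constraint: the slope beyond the last knot equals
the net mass, so zero net mass means flat extension. For additive models
over $D$ features the measure lives on $\{1..D\}\times[0,1]$, each knot
is attached to a coordinate, and net mass must vanish *per coordinate*.
That constraint is what produces feature selection: a linear component
function cannot "escape" the penalty (it is infeasible), so weakly
relevant coordinates end up with no knots at all and are exactly out of
the model.

Losses: squared error $\tfrac12(z-y)^2$; logistic
$\log(1+e^{-zy})$ with $y \in \{-1,+1\}$; and the pseudo-Huber loss
$\ell_\delta(u) = \delta(\sqrt{1+u^2/\delta}-1)$, which is quadratic for
$|u| \ll \sqrt\delta$ and linear with slope $\sqrt\delta$ beyond. The
default $\delta = 0.0015$ puts the quadratic-to-linear transition at
$\sqrt\delta \approx 0.039$, appropriate for responses on a unit scale
with occasional gross outliers.

## The algorithm

The solver is a fully-corrective conditional gradient (Frank–Wolfe)
method applied directly to the measure-space program.

1. **Linear minimization oracle.** At the current predictions, with loss
   gradient $g$, the best extreme point of the constraint set is a
   two-point measure $s^\star = \tfrac\tau2\delta_{t_+} -
   \tfrac\tau2\delta_{t_-}$ where $t_+$ minimizes and $t_-$ maximizes
   the hinge correlation $h(t) = \langle g, \psi(t)\rangle$,
   $\psi(t)_i = (x_i - t)_+$. Because $h$ is piecewise linear with
   breakpoints at the data, both extrema are found *exactly* in one
   $O(n)$ pass over suffix sums of $g$ and $g x$, scanning the candidate
   set $\{0\} \cup \{x_i\}$. For additive models the scan runs per
   coordinate and the best coordinate wins.
2. **Certificate.** The duality gap
   $\langle g, E_x\mu\rangle - \langle g, E_x s^\star\rangle$ bounds the
   true suboptimality of the current iterate; fitting stops when the gap
   falls below `tol_gap * max(1, |objective|)` (scale-free), when the
   oracle proves the zero measure is a conditional gradient (exact
   optimality), or at `max_outer`.
3. **Fully-corrective step.** Both new knots are added and all weights
   are re-optimized at fixed knots, jointly with the unpenalized
   intercept, under the $\ell_1$ budget and per-coordinate sum-zero
   constraints. The polytope's vertices are the paired points
   $\tfrac\tau2(e_i - e_j)$ within one coordinate group (plus the
   origin), and the solver is pairwise-vertex Frank–Wolfe with exact
   line search, accelerated by an equality-constrained "face polish"
   step: fixing the sign pattern of the active weights, a majorized
   Newton direction (using only the loss's global curvature bound —
   pointwise second derivatives are never required) is followed with a
   line search capped before any sign change. The polish never increases
   the objective and leaves the Frank–Wolfe gap as the sole certificate,
   so it is purely an accelerator. The intercept is re-minimized exactly
   after every step, which makes $\partial L/\partial c = 0$ and hence
   lets the measure-block gap bound the *joint* suboptimality by
   convexity.
4. **Pruning.** After each corrective step, duplicate knots are merged
   and knots with $|w| \le$ `w_tol` ($10^{-8}\tau$ by default) are
   dropped. The prune is accepted only if it does not increase the
   objective, so the objective trace is exactly nonincreasing — a raw
   threshold prune can raise it at the $10^{-8}\tau$ scale near
   convergence.

Warm-started paths (`fit_path`) fit an increasing budget grid, each fit
starting from the previous solution (feasible because the budgets
nest); each grid point carries its own certificate.

## Boundary knots and exact saturation

The candidate set includes the scaled maximum ($t = 1$ on training
data), whose hinge column is identically zero on the training points.
Such "slack" knots matter: they absorb net mass at zero prediction cost,
enlarging the feasible function class (for example, the two-point
interpolant $(x)_+ - (x-1)_+$ needs its balancing atom at the boundary).
Saturation still holds exactly — beyond the last knot the slope is the
per-coordinate net mass, which is zero. The fitting loop also uses slack
knots to restore *exact* (to the last bit) per-coordinate balance after
pruning and after the corrective step's floating-point drift, which is
free because their basis columns vanish on the training data. Constant
(zero-range) raw features are mapped to the constant 0.5 in scaled
space; with a stationary intercept their hinge correlations are
identically zero, so they can never acquire knots — the correct
feature-selection behaviour.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `tau` | — | total-variation budget (response units per unit scaled feature); `tau = 0` fits the analytic constant |
| `tol_gap` | `1e-6` | relative duality-gap stopping tolerance of the outer loop |
| `max_outer` | 500 | outer iteration cap (two knots added per iteration) |
| `tol_inner` | `1e-8` | relative Frank–Wolfe gap tolerance of the corrective step |
| `max_inner` | 10000 | corrective iteration cap (warns when hit) |
| `w_tol` | `1e-8 * tau` | knot-pruning threshold, below certificate resolution |
| `delta` | 0.0015 | pseudo-Huber transition parameter ($\sqrt\delta$ = transition residual scale) |

The default budget grid has 16 geometric points spanning three decades
below its upper end. The upper end is twice the largest per-coordinate
TV *estimate* of the interpolant derivative. The estimate matters: the
raw interpolant TV through noisy data scales like $n^2\sigma$ (adjacent
near-duplicate $x$ values produce enormous slopes), which would push the
whole grid far above any statistically useful budget. The estimator
therefore first aggregates blocks of about $n/25$ consecutive sorted
points (means of both $x$ and $y$) and takes the interpolant TV of the
block means; `tv_interpolant(x, y, smooth_window = NULL)` still returns
the exact raw value, which is the budget at which a univariate fit can
interpolate the data exactly.

## The synthetic world

`gen_dataset` draws features uniformly on $[0,1]^D$ and builds a ground
truth that is itself a feasible saturating additive model: each active
coordinate gets `knots_per_active` knots in $(0.05, 0.95)$ with weights
centred to *exact* zero net mass and rescaled to a stated per-coordinate
TV (default 4, an order-one signal against the default noise
$\sigma = 0.1$). Responses are truth plus Gaussian noise; the outlier
mixture adds `outlier_scale * noise_sd` Gaussian contamination to a
seeded subset of exactly `round(outlier_frac * n)` rows (a generic
heavy-tail mechanism — real contamination processes are not modelled);
logistic labels are drawn with probabilities `plogis(truth)`. Everything
is a pure function of the seed (Mersenne-Twister, inversion normals).

What the generator does *not* emulate: correlated or heavy-tailed
feature distributions, heteroscedastic noise, model misspecification
(the truth is exactly representable), and interactions. A green
recovery test therefore establishes correctness of the optimization and
selection machinery under the stated world, not statistical performance
on real data.

The test oracle `gridded_oracle` solves the same objective over the
full candidate knot grid with an *independent* algorithm — FISTA with
adaptive restart over the simplex of paired vertices, with projection —
so agreement between the two solvers cannot come from shared code or
shared failure modes. It deliberately refuses $n > 50$.

## Numerical choices and degenerate inputs

* Ties in the oracle argmin/argmax go to the smallest $t$, then the
  smallest coordinate index, so results are deterministic across
  platforms; the default algorithm uses no randomness at all.
* The logistic loss is computed in softplus form
  ($\max(-m,0) + \log(1+e^{-|m|})$), stable for the large margins that
  occur along a path; the pseudo-Huber value is computed as
  $u^2/(1+\sqrt{1+u^2/\delta})$, algebraically identical to the defining
  form but free of cancellation for $|u| \ll \sqrt\delta$.
* The $\tau = 0$ constant for logistic loss is the full log-odds
  $\log(n_+/n_-)$ — the actual stationary point of
  $\sum_i \log(1+e^{-y_i c})$. (A half-log-odds formula sometimes quoted
  in this context is the *exponential*-loss minimizer.) With separable
  constant fits (all labels equal) the intercept is capped at the
  bracket edge rather than diverging.
* Line searches: closed form for squared loss; derivative bisection to
  $|\varphi'| \le 10^{-10}$ (or 100 iterations) otherwise. Corrective
  returns are clamped to never be worse than their warm start, which
  makes outer objective traces monotone to the last bit.
* All-identical responses under squared loss converge at iteration 0;
  unsorted inputs to the profile routine are an error (sorting is done
  once by the caller).

## Known limitations

* Degree one only; no higher-degree splines or moment constraints, no
  vector-valued (multiclass) measures, no pairwise-interaction bases.
* The regularization path is certificate-exact only at its grid points;
  no provably suboptimal continuous path is constructed.
* Cross-validation helpers are intentionally thin; model selection
  guarantees are out of scope.
* The corrective solver's iteration cap can bite at very large budgets
  (near-interpolation regimes with hundreds of active knots); the fit
  then still returns a valid certificate, just a looser one, and warns.
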