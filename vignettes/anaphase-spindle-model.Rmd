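---
title: "Modelling anaphase B spindle stability with midzone-edge rescue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling anaphase B spindle stability with midzone-edge rescue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anaphaseB)
```

## The model

During anaphase B the fission-yeast spindle elongates because motors slide
the antiparallel interpolar microtubules apart at the midzone. Sliding
consumes the overlap between the two half-spindles, so microtubules must
keep growing or the spindle falls apart. `anaphaseB` implements a minimal
one-dimensional stochastic model of this balance:

* The two spindle pole bodies sit at $\pm S/2$ around a fixed centre and
  slide apart at a constant speed, $S(t) = S_0 + 2 v_s t$. This relation is
  imposed exactly at every step (computed from $t$, not accumulated), so it
  holds to machine precision.
* Each interpolar microtubule is a length with a growing or shrinking
  state (dynamic instability), its minus end pinned at a pole. Growth,
  shrinkage and sliding speeds are constants fitted from live imaging.
* Catastrophe is a multi-step process: the time a rescued microtubule keeps
  growing has CDF $(1 - e^{-\theta t})^n$ — the waiting time for $n$
  independent rate-$\theta$ sub-steps to have all fired. The wild-type fit
  is $\theta = 3.17\,\mathrm{min}^{-1}$, $n = 8.53$, giving a mean of 52.6 s
  and SD 23.4 s (both recomputed by `growth_duration_moments()` and checked
  against the sampler in the test suite).
* The midzone is a fixed-length region centred at the origin; its length is
  drawn once per run from the normal fit
  ($\mu = 1.23\,\mu m$, $\sigma = 0.25\,\mu m$) of measured midzone lengths.
* A fixed budget $R$ of rescue activity distributes along the antiparallel
  overlap. A shrinking microtubule with $n$ antiparallel lattice neighbours
  whose plus end sits at reduced midzone coordinate $x \in [0, 1]$ (0 at the
  midzone edge nearest its own pole) is rescued at rate
  $$r = \frac{n R}{L_m N} P(x; \alpha, \beta),$$
  with $P$ the Beta density and $N$ the current number of antiparallel
  lattice pairs. Because $\int_0^1 P\,dx = 1$ and $\sum_i n_i = 2N$, the
  midzone-integrated total rescue rate is exactly $2R$ whatever the shape
  parameters or the lattice — the budget is conserved as microtubules are
  lost, which is what makes surviving spindles progressively more stable.
* Transverse geometry is a 3×3 chequerboard: five microtubules from one
  pole (corners and centre) interleaved with four from the other, so all 12
  adjacent contacts are antiparallel at the start. When a microtubule
  depolymerises completely, the lattice reorganises: single microtubules
  relocate to empty sites whenever that strictly increases the number of
  antiparallel contacts.
* The spindle collapses when the longest microtubules of the two poles no
  longer overlap.

The `uniform` variant removes midzone organisation (the situation in cells
lacking the Ase1/PRC1 crosslinker): the same budget spreads along the whole
microtubule length, $r = R / (2 L_t)$ anywhere on the spindle, with
$L_t$ the summed microtubule length.

## Parameters

All constants live in a single `sim_params()` object:

| name | meaning | default | units |
|------|---------|---------|-------|
| `v_p` | growth speed | 1.6 | µm/min |
| `v_d` | shrinkage speed | 3.6 | µm/min |
| `v_s` | per-pole sliding speed | 0.35 | µm/min |
| `R` | integrated rescue budget | 55 (34 uniform) | µm/min |
| `theta_cat`, `n_cat` | catastrophe clock | 3.17, 8.53 (2.5, 6.8 uniform) | 1/min, — |
| `mu_mz`, `sigma_mz` | midzone-length fit | 1.23, 0.25 | µm |
| `alpha`, `beta` | rescue localisation | 4, 2 | — |
| `h` | timestep | 0.01 | min |
| `t_max` | simulated duration | 20 | min |
| `S0`, `L_mt0` | initial spindle / microtubule length | 4, 3 | µm |

Defaults are the fitted wild-type values; `sim_params_ase1()` switches the
variant, budget and clock together, and a flat `key: value` config file
(`load_config()`) can override any field. For the uniform preset the
catastrophe-clock values follow the dedicated parameter table
($n = 6.8$, $\theta = 2.5\,\mathrm{min}^{-1}$); the transposed reading
that appears elsewhere can be selected explicitly via `theta_cat`/`n_cat`.

With the wild-type parameters, 500 seeded runs produce no collapse in
20 min, and the mean microtubule count at 15 min is between five and six
(the test suite asserts $5 \pm 1$). Scanning `R` downward raises the
collapse fraction monotonically; at a slow growth speed
(`v_p = 0.5` µm/min) edge-skewed rescue (`alpha = 12`) protects spindles at
least as well as a flat field — a slowly growing plus end rescued deep in
the midzone may catastrophe before leaving it, and skewing the activity
toward the far edge maximises the chance it exits before failing again.

## Stepping rules and their order

One step of length `h` applies, in this fixed order: pole displacement;
growth, catastrophe-clock decrement and catastrophe (clock expired, or plus
end reaching the opposite pole, length clipped to the pole separation);
shrinkage, loss (length ≤ 0, with immediate lattice reorganisation) and
rescue tests at probability $1 - e^{-rh}$; census refresh and collapse
check. State switches take effect from the following step. At
`h = 0.01` min all ordering effects are $O(h)$; a fixed order is chosen for
bit-reproducibility. A shrinking microtubule reaching zero length within a
step is removed outright (the sub-step distance, `v_d * h` = 0.036 µm, is
negligible); simultaneous losses in one step are processed in ascending id
order, each followed by its own reorganisation.

Reorganisation is greedy-until-convergence: all (microtubule, empty site)
moves are enumerated, the strictest improvement applied (ties broken by
lowest microtubule id, then row-major target site), and the search
repeated. The acceptance rule — only moves that strictly increase the
antiparallel contact count — is the modelled biology; the deterministic
search order is ours, chosen for reproducibility since any
maximal-improvement sequence reaches a local optimum of equal quality.

Other numerical conventions: growth durations are sampled by the
closed-form inverse CDF $t = -\ln(1 - u^{1/n})/\theta$ (exact, seedable, no
rejection loop; uniform draws of exactly 0 or 1 are redrawn). The
midzone-length draw is truncated by resampling while ≤ 0.2 µm, removing
unphysical values the unbounded normal admits with tiny probability. The
Beta density at $x \in \{0, 1\}$ is evaluated as its limit. The collapse
comparison is non-strict (zero overlap counts as collapsed) because
crosslinking needs finite overlap. $N$ in the rescue field is the *current*
pair count, recomputed after every loss and reorganisation; a fixed-$N$
alternative would leak budget as microtubules are lost.

## Even loss, and what "constant polymer" means here

Sharing the budget over the overlap makes the rescue rate proportional to a
microtubule's antiparallel neighbour count. When a microtubule is lost its
*antiparallel* neighbours lose a neighbour while same-orientation
microtubules do not, which biases the next loss toward the opposite
orientation. The measurable consequence is that the two poles converge to
the same surviving count — the tests assert that the mean remaining counts
per pole differ by less than 0.5 and that no pole ever empties. Note that
the mean number *lost* per pole differs by about one: the pole that starts
with five microtubules must shed more than the one that starts with four
precisely because the remaining counts equalise.

Total polymer partially tracks spindle elongation (surviving microtubules
span pole to midzone, so their stable length grows with $S/2$), but at the
fitted budget the loss of microtubules offsets this and polymer flattens:
the late/early polymer ratio stays below 2 while the spindle more than
triples in length. At a much larger budget ($R = 150$) no microtubule is
lost and polymer grows steadily; the ensemble test asserts this contrast
rather than near-exact constancy, which a model whose microtubules span
half the spindle cannot produce literally.

## Quantification toolbox

* `bin_by_spindle_length()` — 1-µm binning with per-bin means, the common
  axis for model-data comparison.
* `fit_intensity_scaling()` — the scaling factor between simulated polymer
  and measured fluorescence minimising $\sum_i (s_i - f e_i)^2$; the closed
  form $f = \sum s_i e_i / \sum e_i^2$ is verified against a grid search.
  The printed score in the source material is readable as either
  $s_i - f e_i$ or $s_i - e_i / f$; the two are equivalent under
  $f \to 1/f$ and we adopt the first.
* `ks_distance()` — exact two-sample Kolmogorov–Smirnov distance,
  evaluated at every ECDF step point.
* `fit_catastrophe_cdf()` — least-squares fit of the empirical duration
  CDF to $(1 - e^{-\theta t})^n$, multi-start over moment-guided
  initialisations; recovers generating parameters within 10% at 5,000
  samples.
* `fit_piecewise_elongation()` — the three-phase (prophase, metaphase /
  anaphase A, anaphase B) continuous piecewise-linear fit; for fixed
  breakpoints the remaining parameters are a linear solve, and the
  breakpoints are refined by multi-start Nelder–Mead. Anaphase onset is
  the second breakpoint. Degenerate optima (collapsed middle phase,
  boundary breakpoints, indistinguishable neighbouring slopes) set an
  `unreliable` flag instead of requiring manual intervention.
* `fit_erf_transition()` — the two-state growth-speed transition
  $v(d) = v_\mathrm{fast} - (v_\mathrm{fast} - v_\mathrm{slow})
  (1 + \mathrm{erf}((d - d_0)/w))/2$ against distance-to-pole. The exact
  parameterisation behind the published plateau values is not printed
  anywhere, so recovery tests use this four-parameter form (two plateaus,
  midpoint, width), normalised so $v_\mathrm{fast} \ge v_\mathrm{slow}$,
  $w > 0$.

## Image analysis

Spindle traces are rotated parabolas $g(x) = \alpha x^2$ fitted to
probability maps by maximising
$F = \sum_i P_i^2 \exp(-|\alpha x_i^2 - y_i| / \lambda)$ over pixels with
$P > 0.8$, with $\lambda = 0.55$ µm. The optimiser (not specified in the
source material) is multi-start Nelder–Mead initialised from the
probability-weighted centroid and principal axis of the thresholded
pixels. The curvature is pinned at zero until a trace longer than 6 µm has
been seen, and the sequence fitter is strictly causal — earlier frames are
never refitted after the switch. An optional pair of pole points
constrains the curve through a soft quadratic penalty. Edges are the
extreme projections of $P > 0.6$ pixels onto the curve; the length is the
arc length between them by quadrature of $\sqrt{1 + g'(x)^2}$, verified
against a dense-polyline oracle to 0.1%.

Intensity measurements sample seven parallel curves (normal offsets −3..3
px at 1-px arc spacing, total width 0.77 µm) with bilinear interpolation
(sub-pixel positions; the source material is silent on interpolation), and
subtract per arc-point the median of two flanking 4-px bands — making the
measurement exactly invariant to additive background and linear in signal.
Kymographs take, per frame and arc position, the maximum over the ±3-px
band, and align rows by the centre of mass of the temporal maximum
projection. Coordinates are 0-based and pixel-centred; arc length is
signed from the trace midpoint.

## Synthetic data

Every stage is testable without microscopy through seeded generators that
return data plus ground truth: three-phase elongation series (Gaussian
noise; the noise model is our choice, the source material states none),
growth-event tables (two-state speeds with the error-function mean curve,
durations from the catastrophe clock, rescue positions from the Beta field
on the midzone; distances uniform over 0.5–5 µm, matching the plotted
range), probability-map movies (Gaussian ridge of width 1 px around the
scheduled curve, two pole spots), and intensity series hiding a scaling
factor. What they deliberately do not emulate: point-spread functions,
camera noise statistics, photobleaching, comet superposition, or failed
detections — so passing recovery tests demonstrates correctness of the
estimators on clean structure, not robustness to every artefact of real
movies.

## Problem sizes and runtime

The default test suite runs roughly 2,000 simulations (ensembles of
200–500 runs for the stability claims, 15–40 for the distributional
properties) and completes in a few minutes on one core; 500 wild-type runs
take about a minute. Sampler and fitter checks use $10^4$–$10^5$ draws.
These sizes were chosen so each Monte-Carlo assertion sits several
standard errors away from its threshold.

## Known limitations

* No motors, forces, or crosslinker molecules: sliding is an imposed
  constant, as in the modelled system.
* No microtubule nucleation (absent in this system during anaphase B) and
  no 3-D mechanics.
* The collapse-length distribution for the uniform variant is compared
  between independent ensembles (self-consistency), not to the
  experimental distribution, which would require the microscopy data.
* The decrease of growth speed when plus ends enter the nuclear membrane
  bridge is represented only through the two-state synthetic generator and
  its fitters; the simulator itself uses a single growth speed, as the
  modelled claims require.
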