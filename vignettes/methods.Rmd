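---
title: "Models and methods: emergent exponential fitness-effect distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: emergent exponential fitness-effect distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(dfewave)
```

## The scientific question

Evolution experiments in bacteria and viruses repeatedly find that the
fitness effects of *naturally arising* beneficial mutations follow an
exponential distribution, across organisms whose biology has little in
common. `dfewave` implements a population-genetic explanation: the observable
distribution is not the organism's intrinsic site-by-site distribution of
selection coefficients, $g(s)$, but the product

$$\mathrm{DFE}(s, t) = \langle f(s,t)\rangle\, g(s),$$

where $\langle f(s,t)\rangle$ is the ensemble-average frequency of the
*less-fit* allele at sites with effect $s$ at time $t$ — a beneficial
mutation can only occur where the deleterious allele currently sits. During
adaptation $\langle f \rangle$ becomes exponential in $s$ with a log-slope
$\beta(t) = -\partial \log\langle f\rangle/\partial s$ that grows in time,
and an exponential times the slower-varying $g(s)$ still looks exponential
on a log plot. Whatever shape $g$ has, the observed distribution is driven
toward an exponential. Experiments that count *established* mutations see
$\mathrm{DFE}(s,t)\,\varphi(s)$, with $\varphi(s)$ the fixation probability
(`observed_dfe()` composes all three factors).

## Model

A haploid asexual population of $N$ binary genomes with $L$ sites evolves in
discrete generations. Site $i$ carries $K_i \in \{0,1\}$, with 1 the
less-fit allele of cost $s_i > 0$; log-fitness is additive,
$W = -\sum_i s_i K_i$, and a genome leaves offspring in proportion to $e^W$
(multinomial resampling at constant $N$). Mutation flips each site
symmetrically with per-site probability $\mu$; there is no recombination, so
sites interfere through linkage. Within a generation mutation precedes
selection; at the genomic rates studied ($\mu L = 0.05$) the ordering
changes results only at $O(\mu)$ per generation. Costs are drawn once from
the intrinsic density $g(s)$ — by default the half-normal parameterized by
its mean $s_{av}$,

$$g(s) = \frac{2}{\pi s_{av}} \exp\!\left(-\frac{s^2}{\pi s_{av}^2}\right),$$

and shared across replicate runs so per-site ensemble averages are
meaningful. Exponential and uniform alternatives (same mean) are built in
because the emergent exponential is claimed to be independent of $g$; the
claim can be re-checked by swapping `form` in `intrinsic_dfe()`.

### Two dynamical phases

**Selection of standing variation** ($t \ll 1/s_{av}$). With every site
initially polymorphic at frequency $f_{in}$, selection alone gives

$$\langle f(s,t)\rangle = \frac{f_{in}}{(1-f_{in})e^{ts} + f_{in}},$$

independent of $g$ (`freq_early()`). For small $f_{in}$ this is
$f_{in}e^{-ts}$: exponential with $\beta = t$. The general form is Fermi
occupancy statistics, $f = 1/(e^{\beta s + c} + 1)$ with
$c = \log\frac{1-f_{in}}{f_{in}}$ (`fermi_frequency()`); the identity is
asserted in the test suite for all tested $(s, t, f_{in})$.

**Traveling-wave regime** ($t \gtrsim t_0 \sim 1/s_{av}$). Once clones of
new beneficial mutations dominate, the remaining less-fit alleles sit mostly
at monomorphic sites and are lost by fixation of new beneficial mutations:

$$\frac{\partial \langle f\rangle}{\partial t} = -\mu N \varphi(s) \langle f\rangle,
\qquad
\langle f(s,t)\rangle = f_{in} e^{-t_0 s} e^{-\mu N \varphi(s)(t - t_0)},$$

where $\varphi(s)$ is the fixation probability under clonal interference
(`freq_traveling()`; the closed form is checked against numerical ODE
integration to $10^{-9}$). Expanding the exponent to first order in $s$
gives a log-slope that keeps growing, but slowly:

$$\beta(t) = t_0 + \mu N \varphi'(0)\,(t - t_0).$$

### Fixation probability and the wave closed forms

For a stationary wave with a Gaussian-tailed intrinsic distribution of scale
$s_{av}$, with $U_b$ the beneficial mutation rate per genome per generation:

$$\varphi(s) = \frac{v}{N x_c} e^{-s^2/2v}\,\frac{e^{s x_c / v} - 1}{s},
\qquad
x_c^2 = 2 v \log(N s_{av}),
\qquad
\frac{x_c}{v} = \frac{\log(s_{av}/U_b)}{\sqrt{\pi}\, s_{av}},$$

with $v$ the rate of adaptation and $x_c$ the fitness lead of the
interference boundary. These forms pin $\varphi(0) = 1/N$ (the neutral
limit) exactly and give

$$\varphi'(0) = \frac{x_c}{2 N v} = \frac{\log(s_{av}/U_b)}{2\sqrt{\pi} N s_{av}}.$$

The printed typography of the source relations is ambiguous about radical
placement; the forms above are the unique reading in which the neutral
limit is exact and the three routes to $\varphi'(0)$ (closed form,
$x_c/2Nv$, numerical derivative of $\varphi$) coincide — the package keeps
that triple agreement as a permanent test. A fuller two-term $\varphi$ with
prefactor $A = N^{-1}(x_c/v + 1/x_c)^{-1}$ is available via `full = TRUE`;
the truncation error is below 10% once $x_c^2/v > 10$. The $s \to 0$
singularity of $(e^{s x_c/v}-1)/s$ is handled by series expansion below
$s < 10^{-6} v/x_c$, not by special-casing $s = 0$.

$U_b$ is a parameter, not a constant of nature: beneficial mutations arise
only at less-fit sites, so a natural choice is
$U_b = \mu L \bar f$ (`beneficial_rate()`) evaluated at the wave onset. It
enters only logarithmically. Regime diagnostics
($v/s_{av}^2$, $\log(Ns_{av})/\log^2(s_{av}/U_b)$, $x_c^2/v$) are attached
to every `wave_solution` and printed, as warnings rather than errors: the
reference simulation conditions themselves sit *outside* the deep
multiple-mutation regime ($v/s_{av}^2 \approx 0.5$), and that fact matters
when interpreting the late-time comparisons below.

## Simulation engine and study conditions

`run_simulation()` applies mutation (binomial flip count, uniform placement
— distributionally identical to independent per-entry flips, but $O(k)$)
then multinomial resampling via $e^{W - \max W}$ weights. The default
conditions throughout the package and its tests are the reference setup:
$N = 10^4$, $L = 100$, $\mu L = 0.05$, $f_{in} = 0.2$, half-normal $g$ with
$s_{av} = 0.05$, ensembles of 20 replicates. Replicate $r$ runs with seed
$\texttt{seed} + r - 1$, so ensembles are bit-reproducible and any replicate
can be regenerated in isolation. A dense integer matrix is the state
($10^4 \times 100$); at this size one generation costs ~15 ms, so the
standard 20-replicate, 100-generation ensemble used by the tests and the
acceptance script runs in well under a minute. Clone-compression would pay
only at much larger $N \cdot L$.

`ensemble_mean_frequencies()`, `fit_log_slope()` (OLS of $\log \bar f$ on
$s$; sites with $\bar f = 0$ excluded and counted, since a pseudocount
would bias the slope), `slope_time_series()` and `fit_t0()` turn ensembles
into the observables above. `fit_t0()` is an offset-only fit: the theory
fixes $d\beta/dt = \mu N \varphi'(0)$, so adjusting $t_0$ moves the line
vertically and cannot manufacture agreement in the growth rate.

## What the cross-validation shows — and what it does not

The test suite and `scripts/acceptance.R` recompute, from scratch:

- initialization and landscape means match their targets (binomial /
  half-normal standard errors);
- at $t = 0$ the fitted $\beta$ is zero within its regression error;
- for $t \in [2, 10]$, fitted $\beta(t)$ grows at unit rate. Note that at
  $f_{in} = 0.2$ the early-phase law itself, fitted by the same OLS
  protocol, yields a growth rate of 0.88, not 1 — the logistic form is not
  a pure exponential at this $f_{in}$ — so observed values near 0.9 are the
  theory's own fingerprint, not a simulation deficiency;
- per-site ensemble means at $t = 5, 10$ agree with the standing-variation
  law for ≥95% of sites within three replicate-ensemble standard errors.
  The yardstick is the empirical SE across the 20 replicates: Wright-Fisher
  drift compounds, so per-replicate variance after $t$ generations is of
  order $f(1-f)\,t/N$ (and linkage inflates it further); a single-generation
  binomial SE would be the right scale only at $t = 0$.

The late-time comparison is deliberately kept honest. Over
$t \in [40, 100]$ the fitted $d\beta/dt$ is positive and far below the
early-phase unit rate, as the wave picture requires, but it exceeds
$\mu N \varphi'(0)$ by an order of magnitude at the reference conditions.
Three reasons, all visible in the diagnostics: (i) the closed forms assume
$v \gg s_{av}^2$, which does not hold here; (ii) $\varphi$ is linear only
for $s \ll v/x_c \approx 0.01$, and sites that small are still losing
standing variation (local slope growing at rate ~1) throughout the window,
so no site is simultaneously wave-dominated and in the linear-$\varphi$
regime before $t \approx 100$; (iii) symmetric mutation drives high-cost
sites toward the mutation-selection floor $\mu/s$ inside the window, which
the non-equilibrium theory excludes by construction. The acceptance suite
therefore asserts the full quantitative band and reports its failure rather
than re-tuning conditions; the qualitative claims (slow positive growth,
high-cost sites depleted first, the fitness wave advancing) are all asserted
green.

## Estimating selection coefficients from sequence sets

Given aligned sequences from $\geq 2$ time points (ideally pooled over
replicate populations, which is how data approximate the ensemble average),
`run_inference()`:

1. computes one consensus per position from all sequences pooled across
   time points (a single reference frame keeps estimates comparable across
   times); drops gap-containing columns; maps consensus → 0, any minority
   residue → 1 (`consensus_binarize()`);
2. computes per-site minority frequencies $f_i(t)$; replicate structure may
   be pooled at the sequence level (default) or averaged per replicate;
3. estimates the relative selection coefficient
   $\beta(t)\, s_i = -\log\left[f_i(t)/f_{norm}\right]$
   (`relative_selection()`), in units of $1/\beta$ — the method claims
   relative values only;
4. fixes $f_{norm}$ from the ranked curves $s_{rank}(m, t)$ at two times:
   the estimator factorizes into (time factor) × (site factor), so the two
   curves share a fixed point at the rank of the $s = 0$ site, and
   $f_{norm}$ is the value that zeroes the curves there (`find_fnorm()`).
   Changing $f_{norm}$ by a factor $c$ shifts every estimate by $+\log c$
   and leaves the crossing rank fixed, so the zero condition has a unique
   solution, found in closed form at the interpolated first transversal
   crossing (multiple crossings can arise from noise; the first is used and
   the residual gap is reported);
5. recovers the intrinsic density as the inverse derivative of the ranked
   curve, $g = (\delta s/\delta m)^{-1}$, with tied runs merged before
   inversion (`estimate_intrinsic_density()`).

Design choices a user should know: sites with $f_i = 0$ or $1$ at a used
time point are excluded from ranking and the fixed point (their logs
diverge) and counted in the output; $f_{norm}$ is clamped to $(0,1]$ with a
warning if the fixed point falls outside; a single time point yields
relative estimates against $f_{norm} = \max f_i$ with a warning, since no
fixed point exists. The estimator needs sites on both sides of $s = 0$
(anti-consensus-fitter sites) for the curves to cross; with simulated data
these arise from drift even when all true $s_i > 0$.

### Validation on simulator output

`simulate_alignment_set()` writes per-(replicate, time) FASTA samples plus a
sample sheet — the exact input format of the pipeline — so recovery can be
scored against the true landscape. At the reference conditions (10 replicate
populations, 200 sequences sampled per population at $t = 10$ and $30$),
Spearman correlation between true $s_i$ and estimates is ~0.93–0.96 using
the $t = 10$ estimates among sites with $0.02 \le f_i \le 0.98$ at both
times. The earlier time point is the more reliable one: by $t = 30$ many
sites are fixed *within* populations, so pooled frequencies take effectively
~10 distinct values and rank resolution degrades — a practical lesson that
carries to real data (sample while polymorphism persists). On noiseless
frequencies the pipeline recovers $f_{norm}$ to well under 1% and returns
the half-normal landscape shape exactly (Kolmogorov–Smirnov $p \gg 0.01$ at
$L = 500$).

## What the synthetic data does not emulate

The generator realizes the model's own assumptions: binary alleles, additive
fitness, constant directional selection, constant $N$, no recombination, no
epistasis, exchangeable sites, site-independent $\mu$. Passing recovery
tests therefore shows the estimator inverts the model correctly, not that
real sequence data satisfy the model. In particular: four-state sites with
multiple minority variants, time-varying or balancing selection, shared
phylogenetic ancestry between samples, sampling biases across populations,
and epistatic re-valuation of $s$ over long times are all outside the model;
the pipeline's stated requirements (directional selection; replicate
samples; a population well past its origin but far from mutation-selection
equilibrium) cannot be verified from a single alignment set and must come
from knowledge of the study system.

## Numerical notes

- Tie-breaks: modal-residue ties in the consensus go to character order and
  are flagged; ranking ties go to site order; tied ranked runs are merged
  before density inversion.
- Degenerate inputs error informatively: fewer than 3 estimable sites, ranked
  curves that never cross (all estimates on one side of $s=0$), identical
  time points, all-gap alignments, empty fitting windows.
- `integrate()` handles the intrinsic-density quadrature and the two-term
  $\varphi$; the wave ODE cross-check in the tests uses `deSolve`.
- All tables are TSV with `#` provenance headers (seed, parameters);
  site indices are 1-based in user-facing output.
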