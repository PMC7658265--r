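---
title: "Discrete Turing patterns and chemical computing in coupled glycolytic cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete Turing patterns and chemical computing in coupled glycolytic cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`glycell` simulates and analyses arrays of $N$ continuous stirred tank
reactors ("cells") running the two-variable core model of glycolysis:
an allosteric autocatalytic step (phosphofructokinase, activated by its
product ADP) and a saturating inhibitory feedback. With $x_i$ and $y_i$
the dimensionless ATP and ADP concentrations of cell $i$,

$$
\dot x_i = f_x(x_i, y_i) + q\,k_{ADP} \sum_j \delta_{ij}(x_j - x_i) + p_i(t),
\qquad
\dot y_i = f_y(x_i, y_i) + k_{ADP} \sum_j \delta_{ij}(y_j - y_i),
$$

with reaction terms

$$
f_x = \nu + \sigma_{inh}\frac{y^n}{M^n + y^n}
  - \sigma_M \frac{x(1+x)(1+y)^2}{L + (1+x)^2(1+y)^2},
\qquad
f_y = \phi\,\sigma_M \frac{x(1+x)(1+y)^2}{L + (1+x)^2(1+y)^2}
  - k_s y - \phi\,\sigma_{inh}\frac{y^n}{M^n + y^n}.
$$

The structural matrix $\{\delta_{ij}\}$ encodes the array topology
(linear and cyclic chains, the branched "T" with cell 2 as hub, or any
custom symmetric non-negative matrix), $q$ is the ratio of the ATP to
the ADP transport coefficient and $p_i(t)$ is a piecewise-constant ATP
perturbation (inflow/outflow pulses).

Fixed constants default to the classical allosteric-oscillator values
($\phi = 1$, $\nu = 1.84\,s^{-1}$, $L = 5\times10^6$, $n = 4$, $M = 10$,
$k_s = 0.06\,s^{-1}$); the four routinely varied parameters are
$\sigma_M$, $\sigma_{inh}$, $q$ and $k_{ADP}$, defaulting to the
chemical-computing operating point
($\sigma_M = 100$, $\sigma_{inh} = 35$, $q = 1$, $k_{ADP} = 0.1$).

Two structural facts organise everything else:

* Adding $\phi$ times the $x$ reaction terms to the $y$ reaction terms
  cancels both nonlinearities, leaving
  $\phi\nu - k_s y$. Every uniform stationary state therefore has
  $y^\ast = \phi\nu/k_s \approx 30.67$ exactly, independent of
  $\sigma_M$ and $\sigma_{inh}$; $x^\ast$ is the unique root of
  $f_x(x, y^\ast) = 0$. For small $\sigma_M$ this root can escape to
  infinity (the saturating sink $\sigma_M$ cannot absorb the uptake
  $\nu + \sigma_{inh} h(y^\ast)$); `uniform_steady_state()` reports
  this as the absence of a stationary state, which genuinely happens at
  the $q = 100$, $\sigma_M = 10$ operating point above
  $\sigma_{inh} \approx 8.3$.
* At a uniform state the $2N \times 2N$ Jacobian block-diagonalises
  over the eigenvectors of the graph Laplacian: each Laplacian
  eigenvalue $\mu$ contributes the $2\times 2$ block
  $J_{cell} - \mu\,\mathrm{diag}(q k_{ADP}, k_{ADP})$. The $\mu = 0$
  (uniform) mode reproduces the single cell, which is why the primary
  Hopf loci are independent of both coupling parameters ("two parallel
  lines" in the two-parameter diagrams); the $\mu \neq 0$ modes carry
  the Turing (symmetry-breaking) instabilities.

## Stationary states and their symmetry

`enumerate_states()` runs damped Newton (analytic Jacobian,
Armijo-style step halving, residual tolerance $10^{-10}$) from
Latin-hypercube start points in $[0, 5x^\ast] \times [0, 5y^\ast]$ per
cell, closes the root set under the automorphism group of the array,
and merges duplicates at $10^{-6}$ in the scaled max norm. The box
multiplier 5 comfortably covers observed dynamics (oscillation maxima
reach $y \approx 87 \approx 2.8\,y^\ast$). Multistart enumeration
cannot certify completeness; the $(m, n)$ counts stabilise with the
number of starts and are cross-checked against continuation in the
test-suite.

States are classified by their stabiliser inside the automorphism
group: `uniform`, `symmetric_nonuniform` (fixed by some non-identity
automorphism) or `asymmetric_nonuniform`; orbit size is
$|G|/|\mathrm{stabiliser}|$. A *discrete Turing pattern* is a stable
non-uniform stationary state.

## Continuation and bifurcation detection

`trace_branch()` is a pseudo-arclength predictor–corrector on the
extended system $(s, \alpha)$ with all coordinates scaled (states by
the starting-state magnitude, the parameter by its window width), an
adaptive step in $[10^{-6}, 0.05]$ scaled units, and a full eigensolve
at every accepted point (cheap at $2N \le 8$; eigenvalue tracking
replaces bialternate-product tests by design). Three test functions
are monitored between consecutive points and sharpened by arclength
bisection:

* **fold** — sign change of the parameter component of the tangent;
* **Hopf** — sign change of the largest real part over
  complex-conjugate eigenvalue pairs;
* **branch point** — sign change of the determinant of the bordered
  Jacobian.

On the *uniform* branch the symmetry-breaking modes of highly
symmetric arrays are degenerate (repeated Laplacian eigenvalues: the
3-cycle's $\mu = 3$ is double, the 4-cycle's $\mu = 2$ is double), so
any full-system determinant crosses zero with even multiplicity and
never changes sign. `detect_bifurcations()` therefore additionally
applies the isotypic (Laplacian-mode) decomposition on uniform
segments, testing $\det(J_{cell} - \mu\,\mathrm{diag}(q k_{ADP},
k_{ADP}))$ separately for each distinct $\mu > 0$. This is exact on
the uniform branch and unnecessary off it, where multiplicities are
generically simple.

`switch_branch()` seeds the bifurcating branch along the Jacobian
kernel directions on both sides of a branch point (all kernel
directions are used when the nullspace is multi-dimensional, as at the
degenerate symmetry-breaking points). `solution_diagram()` composes
these pieces recursively — uniform branch, primary switching,
secondary switching — deduplicating branches by automorphism-aware
re-convergence, tracing one representative per orbit and replicating
the images afterwards.

Two-parameter curves (`trace_codim1_curve()`): Hopf curves continue
the minimally augmented system $(F = 0,\ \max\mathrm{Re}\,\lambda_{c}
= 0)$ with finite-difference Newton on fully scaled coordinates; fold
and branch-point curves continue the Moore–Spence bordered system
$(F = 0,\ Jv = 0,\ |v| = 1)$. A Hopf curve terminates when its
frequency falls below $10^{-3}$ (Bogdanov–Takens) and flags points
where more than one pair sits near the imaginary axis (double-Hopf
proximity). Normal-form coefficients are not computed; sub- versus
supercritical character is read off nearby branch behaviour.

## Dynamics, regimes and periods

`simulate_cells()` integrates with `lsoda` (relative tolerance
$10^{-8}$), restarting at every pulse boundary so the discontinuities
of the piecewise-constant perturbation are exact. Concentrations are
intrinsically non-negative here (the uptake terms dominate at the
origin for the amplitudes in use); the integrator nonetheless aborts
if a component falls below $-10^{-9}$.

`classify_regime()` inspects a 2000 s tail window: "stationary" means
per-cell ADP peak-to-peak below $10^{-3}$, "uniform" means relative
inter-cell deviation below $10^{-3}$ — the source material never
defines "settled", so both tolerances are explicit arguments.
`pattern_code()` binarises ADP against $y^\ast$ with a strict
inequality (a tie reads 0). `measure_period()` measures the fast
period as the mean spacing of quadratic-refined large-amplitude maxima
(above the receptor level 80) and the slow period as the spacing of
extrema of the peak-height envelope.

On the slow mode, one caveat discovered while validating: at the
computing operating point the synchronized two-cell oscillation has a
*flat* envelope — with peaks located by root-finding at tolerance
$10^{-12}$ the maxima are constant to $10^{-10}$, the anti-phase
perturbation decays by more than a factor of ten per cycle, and no
small-amplitude slow attractor was found in extensive multistart
surveys over initial conditions and $k_{ADP}$. What a fixed-step
sampling of the trajectory *shows* as a slow envelope (about 300 s at
the default 0.25 s output step) is a stroboscopic alias of the
near-commensurate fast period. The envelope measurement is implemented
exactly as defined and its output on this configuration should be read
with that in mind.

## The chemical computing layer

Pattern coexistence turns an array into a logic gate. The central
knockout system (`gate_config()`, `run_gate_cycle()`,
`truth_table()`) runs a global clock with ticks at
$t_k = 1000k + 600$ s: the input word is applied 100 s *before* a tick
(bit 1 → positive pulse, bit 0 → negative pulse, 100 s), a per-cell
receptor reports oscillations when ADP exceeds 80, the knockout word
fires at the first receptor event after the tick (installing the
gate's base pattern), and outputs are decoded 900 s after the tick. An
output read while the array is still moving is reported as
*unresolved*, never forced to a bit.

Pulse amplitudes for the cyclic arrays are not documented anywhere, so
they are calibrated (script shipped in `inst/scripts/calibrate-gate.R`):
$A_{on} = +1.2$, $A_{off} = -1.0$ converts oscillation into the target
pattern at *every* clock phase of the 3-cell cyclic array, whereas the
$+2.0/-1.0$ pair documented for the three-cell *linear* array works
only at some phases of the cyclic one. The calibrated pair also
reproduces all three printed 3-cell truth tables bit-for-bit and the
4-cell cyclic tables at $\sigma_{inh} = 35$.

Pulse protocols are phase-sensitive in general. The
tautology/contradiction device (a two-cell pair locked into the robust
(1,0) pattern, used as the constant true/false reference) is
initialized from a documented canonical phase — both cells
synchronized on the limit cycle, 11 s past an ADP maximum
(`synced_cycle_state()`) — chosen as the centre of the phase window
for which the whole pulse-length/start-time trade-off line
($\Delta T = 2000 - var$, $t_k = 100 + var$) installs the pattern.

`assemblage` components (gate arrays, the tautology device, a clock
cell with a divide-by-20 counter, two-cell memory pairs) are wired by
*idealized* channels: delayed binary links evaluated cycle-synchronously
in topological order. The excitable-channel chemistry that would carry
these signals in a physical realization is abstracted away (no channel
kinetics are documented), and components exchange signals only — no
inter-component mass transfer. The NAND block is genuinely chemical
but two-stage: an AND-reduced gate (knockout {0 1 1}, third input tied
to 0, cell 1 read) feeding an inverter-reduced gate (knockout
{1 0 1}, cells 1–2 tied to 1, cell 2 read), both advanced one full
knockout cycle per netlist cycle.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run: 5000–6000 s
simulations for periods; the two-cell robustness searches at 0.02
amplitude resolution; 3-cell enumeration with 120–150 multistarts per
node on 2.5-spaced parameter grids; continuation branches capped at
120–250 points; two-parameter curves at 250–400 points. These sizes
keep every quantity stable to well inside its comparison band while
completing in minutes; all are arguments, so larger studies simply
pass bigger values.

Ties and degenerate cases: duplicate stationary states merge at
$10^{-6}$ scaled; fold-versus-branch-point disambiguation falls out of
the separate test functions (a fold changes the tangent sign, a branch
point the bordered determinant); knockout pulses that would overrun
the output-read time are truncated at the read. The multistart seed
and every stochastic component honour one run-level seed.

## What the synthetic configurations do and do not show

All validation inputs are generated by the package itself (no external
data exists for this system): random connected arrays of up to five
cells with brute-force-verified automorphism groups, parameter draws
inside the explored windows, and the documented operating points.
Passing tests demonstrate internal consistency of the solver stack and
agreement with the published dynamical structure — stationary-state
counts, bifurcation locations, truth tables. They do not speak to
phenomena outside the core model: the full 24-reaction glycolytic
chain, pH/temperature dependence of the rate coefficients, stochastic
or delayed coupling, or the reaction–diffusion channels of a physical
assemblage.

## Known limitations

* Enumeration is multistart-based; regions with very fine basins may
  be under-counted (mitigated, not eliminated, by the continuation
  cross-checks).
* Branch tracing can retrace a segment after passing a
  high-curvature fold (duplicates are removed during diagram
  assembly but waste time).
* Limit-cycle branches are obtained by direct simulation only; there
  is no periodic-orbit continuation.
* The slow-envelope period measurement on the synchronized two-cell
  oscillation reflects the sampling strobe discussed above.
* Gate truth tables for the 4-cell arrays at $\sigma_{inh} = 50$ and
  the T-shaped rows (whose $k_{ADP}$ is undocumented and which have no
  stable patterns at $k_{ADP} = 0.1$) are not validated; the cyclic
  $\sigma_{inh} = 35$ configurations are.
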