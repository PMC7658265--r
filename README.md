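# glycell

Simulation and bifurcation analysis of **discrete Turing patterns in
arrays of mass-coupled glycolytic cells**, and the chemical computing
devices built on them.

Each cell is a continuous stirred tank reactor running the two-variable
glycolytic core model (ATP `x` as inhibitor, ADP `y` as activator):

```
dx_i/dt = f_x(x_i, y_i) + q k_ADP Σ_j δ_ij (x_j − x_i) + p_i(t)
dy_i/dt = f_y(x_i, y_i) +   k_ADP Σ_j δ_ij (y_j − y_i)

f_x = ν + σ_inh y^n/(M^n + y^n) − σ_M x(1+x)(1+y)² / [L + (1+x)²(1+y)²]
f_y = φ σ_M x(1+x)(1+y)² / [L + (1+x)²(1+y)²] − k_s y − φ σ_inh y^n/(M^n + y^n)
```

with `{δ_ij}` a symmetric structural matrix (linear, cyclic, T-shaped
or custom arrays) and `p_i(t)` rectangular ATP perturbation pulses.
Depending on `σ_M`, `σ_inh` and the coupling pair `(q, k_ADP)`, stable
non-uniform stationary states — *discrete Turing patterns* — coexist
with uniform oscillations. Targeted pulses switch between them, which
is what the logic-gate layer exploits.

The package is aimed at researchers in nonlinear chemical dynamics and
unconventional computing who want to reproduce, probe or extend this
class of coupled-reactor systems.

## What is inside

* **Model core** — `kinetic_params()`, `cell_topology()`, `cell_rhs()`
  with analytic `cell_jacobian()`, `uniform_steady_state()`
  (`y* = φν/k_s` exactly), topology `automorphisms()`.
* **Dynamics** — `simulate_cells()` (stiff integration, exact pulse
  boundaries), `classify_regime()`, `measure_period()` (fast peaks /
  slow envelope), `pattern_code()`.
* **Stationary states** — multistart `enumerate_states()` with
  symmetry classification and orbit bookkeeping; `newton_state()`,
  `assess_stability()`.
* **Continuation** — pseudo-arclength `trace_branch()`;
  `detect_bifurcations()` (Hopf, fold, symmetry-breaking — including
  the degenerate modes of symmetric arrays via Laplacian-mode
  decomposition); `switch_branch()`; two-parameter
  `trace_codim1_curve()` (minimally augmented Hopf, Moore–Spence
  fold/branch-point) with Bogdanov–Takens and double-Hopf flags;
  `region_map()` (m–n labels); `solution_diagram()`.
* **Chemical computing** — `gate_config()` / `run_gate_cycle()` /
  `truth_table()` / `verify_table()` for the central-knockout logic
  gates; a Boolean expression engine (`eval_boolean()`,
  `infer_expression()`); assemblage components
  (`make_tautology_device()`, `make_clock()`, `make_memory_pair()`,
  `make_gate_array()`, `make_nand_block()`) wired through `netlist()`
  and `simulate_assemblage()`.
* **Workbench** — YAML run configurations (`run_config()`,
  `run_analysis()`), CSV/JSON exporters, `generate_fixtures()`, a CLI
  front end (`inst/scripts/glycell`), `autoplot()` methods and
  broom-style `tidy()`/`glance()`.

## A worked example

Enumerate the stationary states of the three-cell cyclic array at the
chemical-computing operating point, then run one of its logic gates:

```r
library(glycell)

p    <- kinetic_params()            # σ_M = 100, σ_inh = 35, q = 1, k_ADP = 0.1
topo <- cell_topology("cyclic", 3)

st <- enumerate_states(p, topo, n_starts = 150, seed = 42)
glance(st)
#> # A tibble: 1 × 5
#>       m n_stable n_uniform n_symmetric n_asymmetric
#>   <int>    <int>     <int>       <int>        <int>
#> 1     7        3         1           6            0
```

Seven stationary states: the (unstable) uniform state plus two
symmetry-related triplets of non-uniform states, of which one triplet
is stable — the "7-3" region. The three stable patterns carry the
codes `011`, `101`, `110` (ADP above/below `y* = 30.67` per cell).

```r
cfg <- gate_config(p, topo, knockout = c(0, 1, 1))
tt  <- truth_table(cfg)
tt
#> <truth_table> 3-cell gate, knockout {0 1 1}
#>      A1    A2    A3    y1    y2    y3
#> 1     0     1     1     0     1     1
#> 2     1     0     0     0     1     1
#> 3     0     0     1     0     1     1
#> 4     0     1     0     0     1     1
#> 5     1     0     1     1     0     1
#> 6     1     1     0     1     1     0
#> 7     0     0     0     0     1     1
#> 8     1     1     1     0     1     1

verify_table(tt, c("A1 & (A2 ^ A3)", "!(A1 & A3) + A2", "!(A1 & A2) + A3"))$match
#> [1] TRUE
```

Each clock cycle applies the input word as pulses, lets the receptor
(ADP > 80) detect oscillation, fires the knockout word if needed, and
decodes the resulting pattern: per cell the gate computes the Boolean
functions shown, e.g. `A1·(A2 ⊕ A3)` in cell 1.

Single-cell dynamics:

```r
tr <- simulate_cells(p, cell_topology("linear", 1), t_end = 5000)
measure_period(tr, 1, "fast")
#> [1] 50.29193
```

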