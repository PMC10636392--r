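---
title: "Models and methods behind fgba"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fgba}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgba)
```

## The model

`fgba` implements a four-state probabilistic cellular automaton of
tropical vegetation and fire on a periodic square lattice. Each cell is
forest (F), grass (G), burning (B) or ash (A); the dynamics are a
continuous-time Markov chain with spontaneous channels — recruitment
G,A→F at rate β, mortality F→G at γ, ignition G→B at ϕ per grass cell,
extinction B→A at μ, regrowth A→G at λ — and nearest-neighbour channels:
forest spread GF,AF→FF at α and fire spread GB→BB at ρg, FB→BB at ρf,
each per neighbour connection. The default rates (per year) are
α = 3×10⁻², β = 2×10⁻⁴, γ = 2×10⁻², λ = 5, μ = 10⁶, ρg = 9×10⁶,
ρf = 1.11×10⁵, with ϕ of order 1/N so that a handful of fires ignite per
year in the domain. Three empirical facts are encoded: fires ignite only
in grass; fires spread far more easily through grass than into forest
(per-neighbour spread probabilities pg = ρg/(ρg+μ) = 0.9 versus
pf = ρf/(ρf+μ) ≈ 0.1); and fire/regrowth dynamics are orders of magnitude
faster than forest demography. `fgba_params()` warns when this timescale
ordering is broken, because every analytic result in the package leans on
it.

The strong timescale separation makes the system fast–slow: a fire sees a
frozen vegetation map and burns out in hours; forest demography then sees
only the time-averaged effect of many fires. Two geometric observables
carry all of the coupling:

* the forest perimeter `[FG]` — the density of forest–grass neighbour
  pairs, through which forest spreads (gain ∝ α[FG]);
* the grassland-weighted perimeter `[FG]cg = Σⱼ ([G]ⱼ/[G])·[FG]ⱼ` over
  grass clusters j — a fire ignites in cluster j with probability
  proportional to its area and erodes only that cluster's interface, so
  the loss term is ϕ pf N [G] [FG]cg.

The balance equation

d[F]/dt = β[G] − γ[F] + α[FG] − ϕ pf N [G] [FG]cg

is the package's central object (`net_rate()`); it makes no assumption
about spatial structure because `[FG]` and `[FG]cg` are measured on the
landscape at hand.

## Simulator design

`simulate_fgba()` is an exact event-driven (Gillespie) sampler, not a
fixed-step approximation, because the rates span ten orders of magnitude
and any uniform step size would be either wasteful or wrong. The C++ core
keeps one aggregate propensity per cell in a Fenwick tree (O(log N)
sampling and update; an event touches only its own and four neighbouring
cells). Spontaneous ignition is held outside the tree as the scalar
channel ϕ_eff·nG with a maintained list of grass cells: this makes the
feedback-control law (below), which changes ϕ_eff after every event that
changes `[F]`, an O(1) update instead of an O(N) reweighting of all grass
cells. Elapsed time and the running integrals of `[F]` and `[G]` are
accumulated with compensated (Kahan) summation so that ~10⁷ increments of
order 10⁻⁷ years survive double precision; the Fenwick tree is rebuilt
from the exact per-cell rates every 2²⁰ events to cancel drift.

Recording is decoupled from the event stream: state fractions, the
effective ϕ(t) and the exact time-integrals are written on a fixed
cadence (`record_dt`), optionally together with `[FG]`, `[FG]cg`
(one cluster labelling per record) and full snapshots at requested times.
Ignition timestamps and per-channel event counts are always logged. On
lattices of at most 12 cells the engine can also accumulate the exact
time spent in every full lattice configuration; the test suite uses this
to compare a 2×2 run against the stationary distribution of the
brute-force 256-state generator matrix (total-variation distance < 0.05),
which is the strongest exactness check available. Width- or height-2
tori are degenerate: the four directional neighbour slots then count each
of the two distinct neighbours twice, which keeps the lattice 4-regular;
the brute-force oracle uses the same convention because it is part of the
model's definition on such domains.

Reproducibility: every trajectory takes an integer seed and draws from
R's RNG; ensembles derive replicate seeds deterministically from a base
seed. Reruns with identical configuration and seed are byte-identical.

## Single fires and the loss approximation

`simulate_fire_event()` runs the fast subprocess alone (channels G→B,
F→B, B→A on a frozen landscape) until no cell burns. The analytic
counterpart `expected_fire_loss()` gives the expected forest loss per
fire as pf·[FG]ⱼ (linearised) or as the sum of exact exposure
probabilities 1−(1−pf)^[FG]ᵢⱼ. The approximation assumes the fire reaches
the whole interface exactly once (pg→1) and that burning forest cells do
not spread fire onward (pf small); the Monte-Carlo event *does* let
burning forest spread, so the pair quantifies the approximation error. At
the default pf = 0.1 this secondary spread inflates mean losses by
roughly a third on hole-in-forest geometries — the linearised formula is
a genuinely low-pf result — so the quantitative agreement checks in the
test suite are run at pf = 0.005 and pg ≈ 0.999, inside the stated
validity regime, where Monte Carlo, exact-exposure and linearised values
coincide within Monte-Carlo error (10⁴ fires). The same reasoning fixes
the critical-hole test below.

## Emergent one-variable dynamics

Along trajectories at fixed ϕ the scatter of `[FG]` and `[FG]cg` against
`[F]` collapses onto narrow bands: the geometry is slaved to the slowly
varying forest area. `fit_emergent_curves()` fits these steady-state
functions nonparametrically with penalised thin-plate splines
(`mgcv::gam`), which supply pointwise standard errors. Three guard rails
are applied: heavily weighted zero-anchors at F = 0 and F = 1 (no
interface without both cover types), clamping of negative predictions to
zero, and `[FG]cg* ≤ [FG]*` enforced pointwise (independent smoothers do
not guarantee the inequality that holds sample-wise). The smoother must
pass a known-function recovery test (synthetic scatter from a smooth
curve plus noise, maximum error below twice the noise SD) before it is
trusted on simulation output. `ode_steady_states()` then brackets sign
changes of the closed balance on a fine grid restricted to the
data-supported range of `[F]` — extrapolation is refused — refines roots
with `uniroot` and classifies stability by the sign of the numerical
derivative. With curves fitted at ϕN = 0.38 on a 50×50 lattice this
yields two stable states (near 0 and near 0.83) separated by a saddle
near 0.35, i.e. the bistable structure of the full automaton.

When all grass is one cluster, `[FG]cg = [FG]` and the balance reduces to
`single_cluster_net_rate()`; this is accurate for low forest cover
(`[F]` below about 0.2), where most grass belongs to the giant cluster.

For β = γ = 0 a closed forest with a grass hole either recovers or
collapses; the balance gives the critical grass fraction
`[G]c = α/(ϕNpf)` (`critical_hole_size()`). The simulation sweep that
brackets this value is run at pg ≈ 0.999 (ρg raised to 9×10⁸): at the
default pg = 0.9 fires miss part of the interface, which shifts the
empirical threshold some 20–30% above the formula on a 50×50 domain —
again, the formula inherits the whole-interface assumption.

## Resilience

`sensitivity()` evaluates λF = Δ(d[F]/dt)/Δ[F] between a landscape and a
perturbed copy; negative values mean dampening, positive amplification.
`mean_sensitivity()` averages over an ensemble as the ratio of weighted
sums (not the mean of ratios), with weights proportional to the rates of
the natural processes each perturbation mimics: fire-driven removal of
perimeter forest at the largest grass cluster (weight ϕN·pf), perimeter
forest addition (α), scattered mortality (γ) and recruitment (β); 64
realisations by default. The perturbation magnitudes are not dictated by
the theory; the defaults convert 10% of eligible perimeter cells but only
1% of cells for the scattered kinds, so that every kind changes `[F]` by
a comparable small fraction. This keeps perturbed landscapes close to
dynamically generated geometry — large scattered perturbations create
artificially fragmented landscapes far off the emergent manifold whose
huge perimeter gain swamps the fire feedback and biases λ̄F negative.
With these defaults the indicator reproduces the expected pattern at
ϕN = 1.32: amplification at the stabilised saddle, dampening at both
stable states, and a more resilient grassland than forest state. All
evaluations use the slow-timescale vegetation view (B,A→G) for
consistency with the balance equation. Ties for "largest grass cluster"
are broken by the deterministic row-major labelling order.

## Noninvasive feedback control

To measure unstable equilibria the ignition rate is made state-dependent,
ϕ(t) = ϕ₀ + g([F](t) − F_ref), clamped at zero and re-evaluated after
every event (`controlled_simulate()`). At a controlled steady state the
realised pair (ϕ̄, [F]̄) is an equilibrium of the *uncontrolled* system —
the control only reshapes stability — so sweeping F_ref traces the saddle
branch (`trace_branch()`); stable branches come from plain runs started
at all-forest and all-grass. Equilibria are estimated event-exactly:
`[F]̄` as the time integral over the averaging window divided by T (the
engine's compensated integrals, not a sample mean), and
ϕ̄ = (ignition count in window / T) / [G]̄, the realised per-grass-cell
ignition rate. Each point carries a moving-block-bootstrap CI of the
windowed `[F]` series; a point whose control clamped more than half the
time or whose windowed sd exceeds 0.15 is flagged unconverged rather than
reported as an equilibrium. Gains are problem-specific: g > 0 (excess
forest raises fire pressure) with gN ≈ 20 stabilises the saddle near
ϕN = 0.26 on a 50×50 lattice, while the steep upper part of the saddle
branch needs stiffer gains (gN ≈ 100) and a hole-like initial condition;
both are exposed, nothing is hard-wired. Burn-in and window (t0 = 150 y,
T = 250–400 y at 50×50) were sized so that ϕ̄'s Poisson error stays below
~10%. Released from a controlled saddle, plain runs tip to forest or
grassland depending on the seed, and the balance evaluated at ϕ = ϕ̄ on
window snapshots vanishes within noise — the two operational checks of
noninvasiveness in the test suite.

## Mean-field approximations

Assuming spatially uncorrelated forest placement closes the balance as
dF/dt = βG + 4αFG − γF − ϕNpf·G·[FG]cgu(F), with `[FG]` replaced by its
uncorrelated expectation 4F(1−F) (pair-density units carry the factor 4)
and `[FG]cg` by its value on uniform-random landscapes, `[FG]cgu(F)`. No
closed form for `[FG]cgu` is attempted:
`estimate_uncorrelated_weighted_perimeter()` builds a Monte-Carlo table
(default 64×64 lattice — large enough that finite-size bias is small
against the Monte-Carlo SE — with a warning below 16×16) and `mf_rate()`
interpolates it linearly, refusing extrapolation. At low cover grass is
one giant cluster, giving the closed form `mf_low_cover_rate()`, the
stable states F₋* = 0 and F₊* = 1 − γ/(4α) ≈ 0.83, and — from the sign
change of the derivative at F = 0 — the bistability onset
(ϕN)min = (α − γ/4)/pf ≈ 0.25, i.e. a maximum fire return interval of
4 years. The giant-cluster identity degrades sooner than one might hope:
at F = 0.2 rare isolated grass cells already shave a real (not
Monte-Carlo) percent-level deficit off 4F(1−F), so quantitative checks
are made at F ≤ 0.1. Where the automaton's dynamics have acted, forest is
aggregated and `[FG] < 4F(1−F)` (`mf_bias_check()`); the mean field is
therefore trusted only near the uncorrelated stable states, and the
measured-geometry balance is used everywhere else.

## Problem sizes, determinism and limitations

The simulations behind the package's own validation use 50×50 lattices
(2500 cells), 300–600 simulated years, ensembles of 3–20 seeds, 10⁴
single-fire realisations and 64-point mean-field tables; at these sizes
the full test suite runs in about a minute on one core while every
stochastic check retains a ≥3σ margin. All stochastic results are exactly
reproducible from integer seeds. Known limitations: parameters are
spatially homogeneous; dispersal and fire spread are strictly
nearest-neighbour on a square torus (no kernels, wind or anisotropy);
finite domains make macroscopic transitions sharper than they would be on
much larger lattices, and saddle positions measured on 50×50 shift
slightly with domain size; and the uniform-random initial conditions used
to seed ensembles are *not* typical dynamical landscapes — scatter from
their first decades is discarded before curve fitting. Passing tests
demonstrate internal consistency of simulator, balance framework and
mean field under these idealisations, not fidelity to any particular
real landscape.
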