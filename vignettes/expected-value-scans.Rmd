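---
title: "Prior-averaged expected values for reaction-network objectives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior-averaged expected values for reaction-network objectives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evnest)
```

## The problem

Mass-action models of signalling networks depend on dozens of kinetic rate
constants that are rarely measured. Rather than calibrating a single
parameter set, `evnest` asks a different question: *averaged over everything
the rate constants could plausibly be, how strongly does a network execute
its output?* Formally, for a model $M$ with parameters $\theta$, a
simulation objective $\mathrm{Obj}(\theta, M) \in [0, 1]$, and a normalized
prior $P(\theta \mid M)$, the package estimates the expected value

$$Z = \int \mathrm{Obj}(\theta, M)\, P(\theta \mid M)\, d\theta,$$

the exact analogue of Bayesian evidence with the objective standing in for
the likelihood. Because $Z$ integrates over a *normalized* prior, comparing
$Z$ across nested network variants automatically penalises parameter-space
volume the way evidence penalises model complexity. Signed ratios of two
expected values (the EVR, below) then play the role of a Bayes factor for
"which wiring explains execution better under these conditions".

The package applies this machinery to programmed cell death: a reduced
extrinsic-apoptosis network in which the death signal can reach effector
Caspase-3 either directly (initiator Caspase-8 cleaves Caspase-3; the
Type I route) or through the mitochondria (tBid, Bax pore formation,
Cytochrome-c/Smac release, apoptosome; the Type II route), with XIAP as the
pivotal inhibitor of both Caspase-3 and the apoptosome and PARP cleavage as
the proxy for death.

## The nested-sampling estimator

`ns_run()` estimates $Z$ by nested sampling. $N$ live points are drawn from
the prior, each scored by the objective. At iteration $i$ the worst point
(value $L_i$) is removed, the enclosed prior mass shrinks deterministically
to $X_i = e^{-i/N}$, and the removed point contributes
$L_i\,(X_{i-1} - X_i)$ to the running sum — a rectangle rule on the
prior-mass axis. The replacement point is drawn uniformly from the prior
*subject to exceeding the removal threshold*.

Implementation choices that matter:

* **Proposals.** A single bounding ellipsoid of the live points (covariance
  shape, scaled so every live point is inside, squared-radius enlargement
  1.25), intersected with the prior box; candidates are drawn uniformly
  inside it in batches. When the ellipsoid barely intersects the box — the
  early phase, when it typically *contains* the box — or when it is
  degenerate (singular covariance), proposals fall back to whole-prior
  rejection, which is distributionally equivalent there. Multi-ellipsoid
  clustering is deliberately out of scope: the objectives here are smooth
  and effectively unimodal at desk scale.
* **Termination.** The run stops when the largest possible remaining
  contribution, $L_{\mathrm{high}} X_i$, falls below a threshold
  (default $10^{-4}$), or at an evaluation cap. The surviving live set then
  contributes its mean value times the remaining mass $X_{\mathrm{final}}$;
  this final correction makes the constant-objective identity $Z = c$ exact.
* **Plateaus.** Objectives saturate at 0 and 1, so ties at the removal
  threshold are common; the removed point is chosen uniformly among the
  tied ones.
* **Failures.** A parameter draw whose ODE integration fails scores 0 and
  still counts as an evaluation: the integral stays defined over the whole
  prior, and degenerate corners (which cleave no PARP anyway) do not abort
  a run. A run aborts only if more than half of the *initial* population
  fails, which indicates a misconfigured model rather than a hard corner.
* **Error.** The information $H = \sum p_i \ln(L_i/Z)$ accumulated over
  dead and surviving points gives the classic $\sqrt{H/N}$ uncertainty on
  $\ln Z$, propagated to $Z$ as $Z\sqrt{H/N}$. For an all-zero objective the
  error is undefined and reported as 0 with a warning. Replicate-spread
  tests confirm the reported error tracks the empirical standard deviation
  within a factor of ~1.5 at desk scale.
* **Reproducibility.** All randomness flows from the seed in `ns_config()`;
  identical configurations reproduce estimates bit for bit. Evaluations run
  serially.

Priors are per-reaction-class log10-uniform boxes spanning four orders of
magnitude around generic plausible rates: first-order forward and reverse
$[10^{-4}, 10^{0}]\,\mathrm{s}^{-1}$, second-order forward
$[10^{-8}, 10^{-4}]\,(\mathrm{molecules/cell})^{-1}\mathrm{s}^{-1}$,
catalysis $[10^{-1}, 10^{3}]\,\mathrm{s}^{-1}$. A parameter shared between
the full network and a knockout subnetwork keeps the identical range, so
expected values across variants integrate over comparable priors.

## The apoptosis network and its knockouts

`build_full_model()` constructs the reduced extrinsic-apoptosis network:
50 species, 62 elementary reactions, 62 rate parameters, 16 species with
nonzero initial copies. The inventory follows a fixed motif decomposition —
reversible binding (2 reactions), catalysis as bind/unbind/convert (3),
translocation (2) — covering DISC assembly (ligand, receptor, FADD,
procaspase-8 with dimerisation at the complex), the direct Caspase-8 →
Caspase-3 cleavage, the mitochondrial arm (Bid truncation and
translocation, Bax activation and oligomerisation to a tetrameric pore,
Cytochrome-c and Smac export, apoptosome assembly and Caspase-3
activation), Bcl-2-family regulation (Bcl-2 binding tBid and activated
Bax; a Bad-like sensitizer binding Bcl-2, plus one displacement reaction),
the XIAP axis (Caspase-3 sequestration and ubiquitination, apoptosome
sequestration, Smac binding plus one Smac-promoted XIAP-degradation step),
the Caspase-3 → Caspase-6 → Caspase-8 feed-forward loop, and PARP cleavage.

```{r}
build_full_model()
```

Initial copy numbers: the four published anchors are FADD and procaspase-8
at 130,000, the Caspase-3 pool at 21,000 and mitochondrial Smac at 100,000
molecules per cell; the remaining twelve use literature-typical values from
the EARM/Albeck lineage of extrinsic-apoptosis models (ligand 3,000,
receptor 1,000, procaspase-6 10,000, Bid 40,000, Bax 100,000, Bcl-2
20,000, sensitizer 25,000, Cytochrome-c 500,000, Apaf-1 100,000,
procaspase-9 100,000, XIAP 100,000, PARP 1,000,000). They live in one
configuration file (`inst/extdata/initial_copies.yaml`) and every one can
be overridden per run; they are modelling choices, not measured ground
truth for this exact network.

`build_subnetwork()` produces the six in-silico knockouts: A (direct
caspase only), B (caspase + mitochondrial activation, no Smac arm), C
(caspase + Smac-mediated XIAP inhibition, no apoptosome), D (mitochondrial
activation only), E (the complete network), F (full mitochondrial
subnetwork without the direct link). Knocked-out content is *deleted*, not
zeroed: each subnetwork is a smaller model whose expected value integrates
over a genuinely smaller parameter space. Species left without any
reaction are removed with the reactions; parameter ids are preserved so
priors transfer.

## Objectives

Two objectives are implemented, both dimensionless fractions:

* `parp_cleavage()` — the end-point fraction of the conserved PARP moiety
  (free + enzyme-bound + cleaved) that is cleaved. The moiety total is a
  conservation law of the stoichiometry, which `conserved_moieties()`
  verifies.
* `pathway_flux()` — attribution of that cleavage to the direct-caspase or
  mitochondrial route. The model registers two *flux accumulators* — extra
  ODE state components that integrate the instantaneous rate of the
  C8-catalysed and apoptosome-catalysed Caspase-3 activation reactions —
  so cumulative attribution is exact regardless of the output grid. The
  flux sum multiplies, at each output step, the cumulative fraction of
  Caspase-3 activated via the target route by the PARP increment over the
  step, normalised by the PARP total. Before any Caspase-3 exists the
  fraction is defined as 0 (no PARP can have been cleaved). Normalising by
  the PARP total makes the two route fluxes sum exactly to the end-point
  cleavage fraction, so flux curves and cleavage curves share one axis.
  Caspase-3 produced via the Caspase-6 feedback loop is attributed to the
  route of its *immediate* catalyst (C8-catalysed activation counts as the
  caspase route even when that C8 was itself feedback-activated); this is
  the only defensible rule without per-molecule lineage tracking.

Simulations integrate the mass-action ODEs (molecules-per-cell counts, no
compartment-volume corrections, deterministic continuum approximation)
with the stiff sparse-Jacobian `lsodes` solver at rtol = atol = 1e-6 over
a default horizon of 20,000 s with 201 output points; flux objectives use
a finer uniform grid. The horizon is a convention of the
extrinsic-apoptosis modelling literature (cells commit within a few hours)
rather than a published value for this network. On solver failure an
evaluation is retried once at 10x tighter tolerances and then flagged; the
sampler maps flagged evaluations to 0.

## A worked example

A desk-scale estimate for the caspase-only knockout with XIAP removed
(seconds at `n_live = 100`, under a minute at 200):

```{r, eval = FALSE}
net <- build_subnetwork("A", initial = c(XIAP = 0))
obj <- make_objective(net, "parp_cleavage")
est <- ns_run(obj, prior_from_network(net),
              ns_config(n_live = 200, seed = 1))
tidy(est)
```

Scans across regulator settings run one seeded estimate per grid point
(`run_scan()`), with per-point seeds derived deterministically from the
base seed, the variant and the grid index, and optional incremental CSV
output so interrupted scans resume. `evr_table()`, `find_crossing()` and
`find_peak()` post-process the trends; `autoplot()` draws them.

The signed expected-value ratio for two variants is
$\mathrm{EVR} = 1 - Z_2/Z_1$ if $Z_1 < Z_2$ and $Z_1/Z_2 - 1$ if
$Z_1 > Z_2$: antisymmetric, zero at equality, continuous across
$Z_1 = Z_2$, undefined (an error) when either value is below $10^{-12}$.
Crossing detection interpolates linearly between the bracketing grid
points of the first downward crossing; peak detection applies a centred
moving average (default window 5 grid points — a convention; the window is
configurable and 1 gives the raw argmax) with ties resolved to the
smallest regulator value.

## Problem sizes and what the tests show

Production-scale runs in this problem family use 16,000 live points and
hundreds of grid points; those are cluster-scale by construction (the
evaluation count grows linearly with the population). The package's test
and example scale is 100–500 live points with termination tolerance
$10^{-4}$, where a full-network estimate takes on the order of a minute.
At that scale the sampler's own error estimates (~0.01–0.04 on values of
order 0.5) are several times smaller than the qualitative gaps the
apoptosis analysis interprets, so ordering checks (e.g. caspase-only vs
complete network at moderate XIAP) are meaningful; precise crossing and
peak locations carry a few grid steps of uncertainty on the coarse grids
the tests use.

The analytic fixtures (`constant`, `linear`, `gaussian2d`, `chain3`,
`toy_inhibitor`) pin the estimator against closed forms, deterministic
quadrature and an independent fixed-step integrator. What passing at desk
scale does *not* show: behaviour of the estimator on strongly multimodal
objectives (the single-ellipsoid proposal would be inefficient there), and
the paper-scale precision of crossing locations, which requires the
production population and grid resolution.

## Known limitations

* The reaction inventory matches the published *counts* and mechanism
  description; the original model's exact reaction list and calibrated
  parameters are not distributed in print, so per-reaction identity is a
  reconstruction. Quantities that depend on fine kinetic detail (exact
  crossing locations) can differ from the published curves by tens of
  percent; structural and ordering results reproduce robustly.
* Stochastic (SSA) simulation, rule-based compilation, spatial effects,
  posterior samples and importance nested sampling are out of scope.
* The SBML dialect covers elementary mass-action kinetic laws only (which
  is all the package ever writes); arbitrary third-party SBML is rejected
  with a clear error rather than silently misread.
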