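# evnest

Prior-averaged expected values for mass-action reaction networks by nested
sampling, applied to Type I / Type II execution of extrinsic apoptosis.

## The problem

Kinetic models of signalling networks depend on rate constants that are
mostly unmeasured. `evnest` sidesteps single-parameter-set calibration and
instead computes, for a network *M*, an objective Obj(θ, M) ∈ [0, 1] and a
normalized prior P(θ | M) over the rate constants,

    Z = ∫ Obj(θ, M) P(θ | M) dθ

— the expected value of the simulated outcome over everything the kinetics
could plausibly be, estimated with the same nested-sampling machinery used
for Bayesian evidence (live points, prior-mass shrinkage X_i = e^(−i/N),
rectangle-rule accumulation Σ L_i (X_{i−1} − X_i), ellipsoidal proposals,
termination when L_high·X_i drops below tolerance). Because the prior is
normalized, Z inherits evidence's built-in complexity penalty, and signed
ratios of two Z values (EVR, a Bayes-factor analogue) compare network
wirings directly.

The package ships a reduced extrinsic-apoptosis network (50 species, 62
mass-action reactions, 62 rate parameters, 16 nonzero initial species:
DISC assembly, direct Caspase-8 → Caspase-3 cleavage, the mitochondrial
tBid/Bax/Cytochrome-c/Smac/apoptosome arm, Bcl-2-family regulation, the
XIAP axis, the Caspase-3→6→8 feed-forward loop, PARP execution), its six
in-silico knockout subnetworks, two objectives (end-point PARP-cleavage
fraction; per-pathway Caspase-3 flux attribution via exact ODE
accumulators), regulator-scan drivers, crossing/peak detection and a
precision-versus-cost study. Who it is for: modellers who want qualitative
network-execution comparisons — which route carries the death signal, and
under which regulator abundances — without pretending to know the kinetics.

## Worked example

Expected PARP cleavage for the direct-caspase knockout with XIAP removed,
averaged over the per-class log10-uniform kinetic priors:

```r
library(evnest)
net <- build_subnetwork("A", initial = c(XIAP = 0))   # caspase-only knockout
obj <- make_objective(net, "parp_cleavage")
est <- ns_run(obj, prior_from_network(net), ns_config(n_live = 200, seed = 1))
est
#> <ev_estimate> Z = 0.999321 +/- 0.00027 (4513 evaluations, 200 live, threshold)
```

Read: averaged over four orders of magnitude of uncertainty in every rate
constant, this wiring cleaves essentially all PARP by 20,000 s — apoptosis
execution is structurally robust when its inhibitor is absent. Raising
XIAP pulls the value down; scanning it maps the inhibition curve:

```r
spec <- scan_spec(c("A", "E"), "XIAP", c(0, 50000, 100000),
                  config = ns_config(n_live = 100, seed = 1),
                  overrides = c(Bcl2 = 0))
scan <- run_scan(spec)
evr_table(scan, numerator = "E", denominator = "A")
autoplot(scan)
```

At moderate XIAP the complete network (E) holds a higher expected cleavage
than the caspase-only knockout (A) — the mitochondrial arm buys resistance
to XIAP, the signature of Type II execution; positive EVR values quantify
that preference. `find_crossing()` locates the half-inhibition XIAP level
of each curve and `find_peak()` the EVR optimum.

A thin CLI over the same functions lives at `inst/cli/evnest.R`
(`model`, `sample`, `scan`, `evr`, `precision`, `export` verbs; YAML
configs via `load_config()`, models exportable to SBML/YAML).

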