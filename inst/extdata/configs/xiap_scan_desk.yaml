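# Desk-scale XIAP scan: 9 grid points, moderate population.
model: full
variants: [caspase, mito_full, full]
objective: parp_cleavage
regulator: XIAP
values: {from: 0, to: 200000, by: 25000}
n_live: 500
termination_tol: 0.0001
seed: 1
overrides: {Bcl2: 0}
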