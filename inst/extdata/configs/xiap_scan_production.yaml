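# Production-scale XIAP scan at the published resolution (cluster-scale:
# 801 grid points per variant at 16,000 live points).
model: full
variants: [caspase, caspase+mito_act, caspase+xiap_inh, mito_act, full, mito_full]
objective: parp_cleavage
regulator: XIAP
values: {from: 0, to: 200000, by: 250}
n_live: 16000
termination_tol: 0.0001
seed: 1
overrides: {Bcl2: 0}
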