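# Default initial copy numbers (molecules per cell) for the reduced
# extrinsic-apoptosis network.  FADD, pC8, pC3 and Smac_m follow published
# values for the model (130,000 / 130,000 / 21,000 / 100,000); the remaining
# species use literature-typical values from the EARM/Albeck lineage of
# extrinsic-apoptosis models and are configurable via build_full_model().
L: 3000          # death ligand (TRAIL/FasL-scale dose)
R: 1000          # death receptor
FADD: 130000     # DISC scaffold
pC8: 130000      # procaspase-8
pC3: 21000       # procaspase-3 (effector pool)
pC6: 10000       # procaspase-6 (feed-forward loop)
Bid: 40000       # BH3 activator
Bax: 100000      # pore effector
Bcl2: 20000      # anti-apoptotic guardian
Bad: 25000       # sensitizer (inhibits Bcl-2)
CytoC_m: 500000  # mitochondrial Cytochrome c
Smac_m: 100000   # mitochondrial Smac/DIABLO
Apaf: 100000     # Apaf-1
pC9: 100000      # procaspase-9
XIAP: 100000     # X-linked inhibitor of apoptosis
PARP: 1000000    # Caspase-3 substrate; cleavage proxies cell death
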