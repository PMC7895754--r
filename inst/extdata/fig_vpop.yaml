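# virtual macrophage population under hypoxia
model: reference
n: 100            # virtual cells
sigma: 0.15       # log10-sd of kinetic-parameter multipliers
o2: 2
duration: 24
t: 24             # phenotype-classification time
seed: 11
out: vpop.tsv
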