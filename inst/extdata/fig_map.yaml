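# polarization-map workflow: 7 single + 21 pairwise stimulation conditions
# at 4/24/48 h on the curated reference network
model: reference
dose: 10          # ng/mL per cytokine
duration: 48      # hours
times: [4, 24, 48]
in_vivo: false    # true rescales every dose 100-fold down (high pg/mL)
out: map.tsv
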