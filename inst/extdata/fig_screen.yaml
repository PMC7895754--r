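# PRCC sensitivity screen of the 24-h M1/M2 score integral under hypoxia
model: reference
o2: 2             # percent O2
duration: 24
n: 100            # LHS samples (raise to >= 10x number of parameters)
seed: 7
out: prcc.tsv
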