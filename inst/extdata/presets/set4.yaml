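# Interaction parameter preset "set4": vanishing cell-hydrogel interfacial
# tensions (gamma_12 = gamma_13 = 0), so no adhesion-driven aggregation.
name: set4
eps: [0.0, 0.8, 2.4, 3.2, 0.0, 0.0, 0.0, 1.6, 2.0, 2.1]
p2: 2.0e-4
p3: 2.4e-4
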