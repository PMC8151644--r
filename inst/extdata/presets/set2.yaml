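# Interaction parameter preset "set2": like set1 but weaker cancer-
# peritumoral adhesion (gamma_23 = 0.7), so peritumoral cells spread on the
# surface of cancer-cell spheroids instead of infiltrating them.
name: set2
eps: [0.0, 0.8, 2.4, 3.2, 0.0, 0.0, 0.0, 0.9, 0.8, 2.1]
p2: 2.0e-4
p3: 2.4e-4
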