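# Interaction parameter preset "set3": equal cell cohesions; heterotypic
# aggregation with neither population wrapping the other.
name: set3
eps: [0.0, 0.6, 2.8, 2.8, 0.0, 0.0, 0.0, 1.2, 1.2, 2.2]
p2: 2.0e-4
p3: 2.4e-4
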