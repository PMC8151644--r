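# Interaction parameter preset "set5": weak cancer-cell cohesion; peritumoral
# cells aggregate while cancer cells roam the hydrogel and escape into the
# surrounding medium.
name: set5
eps: [0.0, 1.4, 2.2, 0.8, 0.0, 0.0, 0.0, 1.4, 0.7, 0.2]
p2: 2.0e-4
p3: 2.4e-4
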