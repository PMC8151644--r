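# Interaction parameter preset "set1".
# eps lists works of cohesion/adhesion in units of ET, canonical order
# e00,e11,e22,e33,e01,e02,e03,e12,e13,e23. Interfacial tensions are always
# derived, never stored. Outcome: heterotypic aggregation with infiltration
# of peritumoral cells into the tumor spheroid (negative gamma_23).
name: set1
eps: [0.0, 0.8, 2.4, 3.2, 0.0, 0.0, 0.0, 0.9, 0.8, 3.1]
p2: 2.0e-4
p3: 2.4e-4
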