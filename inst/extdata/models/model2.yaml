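# Model 2 -- second calibration round (package-authored synthetic stand-in).
# Relative to model1: adjusted alpha-glucan phosphorylase keq (stronger
# product back-pressure, slowing late-phase uptake) and reduced synthase
# C_bind (stronger loss of synthase activity at high PHB), the two
# parameters revisited in the second fitting round. Vmax values are
# placeholders: scenarios overwrite them.
model: model2
reactions:
  aGP:
    vmax: 1.0
    keq: 0.25
    km: {MD: 150.0, Pi: 2.0, G1P: 0.5}
  PGM:
    vmax: 1.0
    keq: 17.0
    km: {G1P: 0.1, G6P: 0.5}
  PGI:
    vmax: 1.0
    keq: 0.3
    km: {G6P: 0.2, F6P: 0.2}
  G6PDH:
    vmax: 1.0
    km: {G6P: 0.1, NADP: 0.02}
  6PGDH:
    vmax: 1.0
    km: {6PG: 0.1, NADP: 0.02}
  RPE:
    vmax: 1.0
    keq: 1.5
    km: {Ru5P: 0.5, Xu5P: 0.5}
  RPI:
    vmax: 1.0
    keq: 0.4
    km: {Ru5P: 0.5, R5P: 0.5}
  TK1:
    vmax: 1.0
    keq: 1.2
    km: {Xu5P: 0.2, R5P: 0.2, S7P: 0.2, G3P: 0.2}
  TK2:
    vmax: 1.0
    keq: 10.0
    km: {Xu5P: 0.2, E4P: 0.2, G3P: 0.2, F6P: 0.2}
  TAL:
    vmax: 1.0
    keq: 1.1
    km: {S7P: 0.5, G3P: 0.5, E4P: 0.5, F6P: 0.5}
  TIM:
    vmax: 1.0
    keq: 22.0
    km: {G3P: 0.5, DHAP: 0.5}
  ALD:
    vmax: 1.0
    keq: 12.0
    km: {DHAP: 0.5, G3P: 0.5, F16P: 0.1}
  FBP:
    vmax: 1.0
    km: {F16P: 0.05}
  XPK:
    vmax: 1.0
    km: {Xu5P: 0.3, Pi: 0.5}
  FPK:
    vmax: 0.12
    km: {F6P: 0.3, Pi: 0.5}
  PTA:
    vmax: 1.0
    keq: 40.0
    km: {AcP: 0.3, CoA: 0.05, AcCoA: 0.2, Pi: 2.0}
  PhaA:
    vmax: 1.0
    keq: 4.0e-5
    km: {AcCoA: 0.3, AcAcCoA: 0.05, CoA: 0.1}
  PhaB:
    vmax: 1.0
    km: {AcAcCoA: 0.001, NADPH: 0.02}
  PhaC:
    vmax: 1.0
    km: {HBCoA: 0.05}
    c_bind: 100.0
    "n": 2.0
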