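# Model 0 -- pre-calibration parameter set (package-authored synthetic
# stand-in). keq values are literature-magnitude equilibrium constants for
# the individual steps (mM mass-action units); Km values are BRENDA-magnitude
# where a typical value is well known and 0.1 mM by default otherwise, with
# deliberately conservative (large) Km for the phosphoketolase,
# transketolase, PTA and reductase steps prior to calibration. Vmax values
# are placeholders: scenarios overwrite them via set_vmax().
model: model0
reactions:
  aGP:
    vmax: 1.0
    keq: 0.4
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
    km: {Xu5P: 2.0, R5P: 2.0, S7P: 2.0, G3P: 2.0}
  TK2:
    vmax: 1.0
    keq: 10.0
    km: {Xu5P: 2.0, E4P: 2.0, G3P: 2.0, F6P: 2.0}
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
    km: {Xu5P: 5.0, Pi: 1.0}
  FPK:
    vmax: 0.12
    km: {F6P: 5.0, Pi: 1.0}
  PTA:
    vmax: 1.0
    keq: 40.0
    km: {AcP: 2.0, CoA: 0.2, AcCoA: 0.2, Pi: 2.0}
  PhaA:
    vmax: 1.0
    keq: 4.0e-5
    km: {AcCoA: 0.4, AcAcCoA: 0.1, CoA: 0.1}
  PhaB:
    vmax: 1.0
    km: {AcAcCoA: 0.05, NADPH: 0.02}
  PhaC:
    vmax: 1.0
    km: {HBCoA: 0.1}
    c_bind: 1000.0
    "n": 1.0
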