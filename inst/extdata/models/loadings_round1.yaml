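round: 1.0
model: model1
description: Loadings selected by the first parameter-scan round (package-computed).
vmax:
  aGP: 4.0
  PGM: 3.0
  PGI: 3.0
  G6PDH: 1.0
  6PGDH: 5.0
  RPE: 4.0
  RPI: 3.0
  TK1: 4.0
  TK2: 4.0
  TAL: 5.0
  TIM: 1.0
  ALD: 2.0
  FBP: 1.0
  XPK: 5.0
  FPK: 0.6
  PTA: 5.0
  PhaA: 5.0
  PhaB: 5.0
  PhaC: 8.0
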