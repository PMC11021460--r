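round: 2.0
model: model2
description: Loadings selected by the second parameter-scan round (package-computed).
vmax:
  aGP: 5.0
  PGM: 2.0
  PGI: 2.0
  G6PDH: 1.0
  6PGDH: 2.0
  RPE: 2.0
  RPI: 1.0
  TK1: 3.0
  TK2: 3.0
  TAL: 3.0
  TIM: 1.0
  ALD: 2.0
  FBP: 1.0
  XPK: 5.0
  FPK: 0.6
  PTA: 5.0
  PhaA: 5.0
  PhaB: 5.0
  PhaC: 5.0
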