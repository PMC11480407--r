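version: mg1655-default-1
rules:
  G:
  - C
  - U
  C:
  - G
  A:
  - U
  U:
  - A
  - G
  cmo5U:
  - A
  - C
  - G
  - U
  mcmo5U:
  - A
  - C
  - G
  - U
  mnm5U:
  - A
  - G
  I:
  - A
  - C
  - G
  - U
  k2C:
  - A
  ac4C:
  - G
  Q:
  - C
  - U
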