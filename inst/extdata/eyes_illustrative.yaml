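AME.R:
- - -15.0
  - 15.0
AME.L:
- - -15.0
  - 15.0
ALE.R:
- - 30.0
  - 110.0
ALE.L:
- - -110.0
  - -30.0
PLE.R:
- - 60.0
  - 160.0
PLE.L:
- - -160.0
  - -60.0
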