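{
  "reference_id": "syn001",
  "P1": [60, 65, 70, 120, 125, 130, 180, 185],
  "P2": [75, 80, 85, 140, 145, 150, 200, 205]
}
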