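{
  "_comment": "RECONSTRUCTED area map for the Medicago sativa CHS2 reference numbering. The published Area 1-4 residue ranges are defined in the structural CHS/STS comparison literature and are NOT reproduced verbatim here: these ranges are approximate anchors only (Area 1 contains Met98; Area 2 contains Thr132 and the TTSGVDM motif). Verify every range against the structural reference before using this map on real sequences. Synthetic benchmarks use their own map (synthetic_area_map()).",
  "reference_id": "MsCHS2",
  "segments": [
    { "name": "Area1", "start": 94, "end": 105 },
    { "name": "Area2", "start": 128, "end": 140 },
    { "name": "Area3", "start": 192, "end": 203 },
    { "name": "Area4", "start": 262, "end": 273 }
  ]
}
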