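{
  "_comment": "Prediction regions for the beta-2 adrenergic receptor, author residue numbering. G protein: mean dRMSF over the lower half of helix 6 (6.27-6.48) and mean dPCC over helix6 x helix3 (3.36-3.50) C-alpha cross pairs. Beta-arrestin: mean dRMSF over the helix 1 set (1.49,1.51,1.52,1.55) plus helix 7 (7.50-7.52), mean dPCC over helix1-set x helix 7 (7.46-7.52).",
  "gprotein": {
    "rmsf_region": [265, 266, 267, 268, 269, 270, 271, 272, 273, 274, 275, 276, 277, 278, 279, 280, 281, 282, 283, 284, 285, 286],
    "pcc_region_a": [265, 266, 267, 268, 269, 270, 271, 272, 273, 274, 275, 276, 277, 278, 279, 280, 281, 282, 283, 284, 285, 286],
    "pcc_region_b": [117, 118, 119, 120, 121, 122, 123, 124, 125, 126, 127, 128, 129, 130, 131]
  },
  "barrestin": {
    "rmsf_region": [50, 52, 53, 56, 323, 324, 325],
    "pcc_region_a": [50, 52, 53, 56],
    "pcc_region_b": [319, 320, 321, 322, 323, 324, 325]
  }
}
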