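{
  "_comment": "State monitors for the beta-2 adrenergic receptor: helix3-helix6 C-alpha distance (Arg131-Leu272), NPxxY backbone RMSD (residues 322-327) and connector heavy-atom RMSD (3.40/6.44).",
  "distance_residues": [131, 272],
  "npxxy_residues": [322, 323, 324, 325, 326, 327],
  "connector_residues": [121, 282]
}
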