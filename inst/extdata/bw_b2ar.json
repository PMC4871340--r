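{
  "_comment_": "Ballesteros-Weinstein labels for the beta-2 adrenergic receptor residues used by the region definitions and state monitors.",
  "44": "1.43",
  "50": "1.49",
  "52": "1.51",
  "53": "1.52",
  "56": "1.55",
  "79": "2.50",
  "113": "3.32",
  "117": "3.36",
  "121": "3.40",
  "122": "3.41",
  "131": "3.50",
  "265": "6.27",
  "268": "6.30",
  "271": "6.33",
  "272": "6.34",
  "275": "6.37",
  "278": "6.40",
  "282": "6.44",
  "285": "6.47",
  "286": "6.48",
  "319": "7.46",
  "322": "7.45",
  "323": "7.50",
  "324": "7.51",
  "325": "7.52",
  "327": "7.54"
}
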