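{
  "motility": {
    "delta_ct": [["let-7c-5p"], ["miR-25-3p"], ["miR-100-5p"], ["miR-204-5p"], ["U6"], ["miR-92a-3p"], ["miR-26a-5p"]],
    "genorm": [["let-7c-5p", "U6"], ["miR-25-3p"], ["miR-204-5p"], ["miR-92a-3p"], ["miR-100-5p"], ["miR-26a-5p"]],
    "normfinder": [["let-7c-5p"], ["miR-100-5p"], ["miR-25-3p"], ["miR-204-5p"], ["U6"], ["miR-92a-3p"], ["miR-26a-5p"]],
    "bestkeeper": [["U6"], ["let-7c-5p"], ["miR-25-3p", "miR-26a-5p"], ["miR-92a-3p"], ["miR-100-5p"], ["miR-204-5p"]]
  },
  "morphology": {
    "delta_ct": [["miR-92a-3p"], ["let-7c-5p"], ["miR-100-5p"], ["miR-25-3p"], ["miR-204-5p"], ["U6"], ["miR-26a-5p"]],
    "genorm": [["miR-92a-3p", "let-7c-5p"], ["miR-100-5p"], ["miR-25-3p"], ["U6"], ["miR-204-5p"], ["miR-26a-5p"]],
    "normfinder": [["miR-92a-3p"], ["let-7c-5p"], ["miR-100-5p"], ["miR-25-3p"], ["miR-204-5p"], ["U6"], ["miR-26a-5p"]],
    "bestkeeper": [["U6"], ["miR-92a-3p"], ["let-7c-5p"], ["miR-25-3p"], ["miR-100-5p"], ["miR-204-5p"], ["miR-26a-5p"]]
  }
}
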