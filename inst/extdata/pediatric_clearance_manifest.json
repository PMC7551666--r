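{
  "total_records": 75,
  "observations": {
    "monoclonal": 33,
    "polyclonal": 21,
    "non_antibody": 21
  },
  "drugs": {
    "monoclonal": 13,
    "polyclonal": 7,
    "non_antibody": 9
  }
}
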