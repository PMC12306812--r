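# Guinea-pig OHC at the 4 kHz place (40 um cell), physical mode.
# Quantities may be bare SI numbers or "value unit" strings.
label: guinea-pig-4khz
physical:
  q: "-0.8 e"
  a: "0.67e-4 nm"
  "N": 3.0e7
  C0: "30 pF"
  sigma: "10 nS"
  i0: "0.3 nA"
  ko: "17 mN/m"
  Ke: "20 mN/m"
  gx: "-0.04 1/nm"   # magnitude 1/(25 nm); negative sign = amplifying feedback
  eta: "0.8e-7 N s/m"
  fr: "4 kHz"
  connectivity: series
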