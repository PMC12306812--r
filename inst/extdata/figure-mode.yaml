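# Dimensionless sweep mode: the groups the published reference sweeps use
# (guinea-pig 4 kHz electrical/elastic groups, omega_bar_eta pinned to 10).
label: guinea-pig-4khz (figure mode)
dimensionless:
  ua: 0.13818143408981173
  Kbar_e: 0.5405405405405405
  omega_bar_eta: 10
  omega_bar_m: 0.013262911924324614
  g: -36.94054054054055
  chi: 0.9888942539835825
  a1: 0.11355421781774185
  connectivity: series
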