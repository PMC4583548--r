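# Truncation study: same problem as colonization-success.yaml; pair with the `truncation`
# subcommand, e.g. --x 0 --t 20 --terms 1,2,5,10,100.
growth: {kind: exponential, L0: 1.0, alpha: 0.1}
lineage:
  k: [0.1, 0.2, 0.3, 0.0]
  m: 2
diffusivity: 1.0e-2
initial_condition: {kind: block, C0: 1.0, gamma: 0.2}
method: series
terms: 1000
times: [20]
grid: {kind: xi, points: 101}
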