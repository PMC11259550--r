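# Bundled demo cohort: 250 samples x 2000 probes, sized to run end-to-end
# on a single CPU in a few minutes.
outDir: epiage_demo
simulate:
  nSamples: 250
  nProbes: 2000
  fracUp: 0.05
  fracDown: 0.10
  noiseSd: 0.03
thresholds:
  nPerm: 100
clock:
  alphaGrid: [0.1, 0.3, 0.5, 0.7, 0.9]
  multimodal:
    enabled: true
    maxSamples: 20
    alphaGrid: [0.2, 0.5, 0.8]
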