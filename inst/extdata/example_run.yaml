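# Example pipeline configuration: equimolar mixture of two barcoded
# carriers, one probe matching the wild-type overhang, the mutant overhang
# carrying a seed-region mismatch at position 1.
seed: 42
n_events: 200
sim:
  folded_fraction: 0.7
  knot_rate: 0.045
probes:
  - name: probe_wt
    spacer: GCUGGAGCAGAUGGGCUUGU
designs:
  - name: wildtype
    barcode: "11111"
    concentration_weight: 1
    probe: probe_wt
    overhangs:
      - position: 0.1
        protospacer: GCTGGAGCAGATGGGCTTGT
        pam: TGG
  - name: mutant
    barcode: "11001"
    concentration_weight: 1
    probe: probe_wt
    overhangs:
      - position: 0.1
        protospacer: ACTGGAGCAGATGGGCTTGT
        pam: TGG
binding_model:
  baseline_efficiency: 0.337
  no_pam_probability: 0
detect:
  threshold_sigma: 5
  min_duration: 2.0e-4
  max_noise_pA: 15
peaks:
  threshold: 30
  height: 60
  min_distance: 0.05
  prominence: 60
quantify_mode: efficiency_corrected
save_trace: false
save_events: false
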