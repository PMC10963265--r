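# Default binding-probability multipliers for single mismatches, expanded
# to a full (position, wobble) table by loadMismatchRatios(). Illustrative
# placeholders exposed as configuration, not measured truths.
seed_boundary: 12
seed_mismatch: 0.1
seed_wobble: 0.6
distal_mismatch: 0.9
distal_wobble: 0.9
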