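# Literature critical-N dilution curve constants (Nc = A1 * W^-A2),
# for side-by-side comparison with newly fitted curves.
- label: "winter wheat leaf (Yao et al. 2014)"
  basis: leaf
  A1: 3.06
  A2: 0.15
  provenance: published-constant
- label: "winter wheat shoot (Justes et al. 1994)"
  basis: shoot
  A1: 5.35
  A2: 0.442
  provenance: published-constant
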