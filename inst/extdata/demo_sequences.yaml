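- label: DRd+PVd+Kd+Vd
  lines: [DRd, PVd, Kd, Vd]
- label: VMP+DRd+Pd+Kd
  lines: [VMP, DRd, Pd, Kd]
- label: Rd+VCd+Pd+D
  lines: [Rd, VCd, Pd, D]
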