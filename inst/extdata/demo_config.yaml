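curves: synthetic_demo_curves.yaml
sequences: demo_sequences.yaml
attrition: demo_attrition.tsv
optimal: DRd+PVd+Kd+Vd
out_dir: seqmm_demo_out
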