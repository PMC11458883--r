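sequence	role	pfs_l1	pfs_l2	pfs_l3	pfs_l4	os
VMP+DRd+Pd+Kd	common	1.97	4.74	0.46	0.42	7.59
VMP+DRd+Kd+Pd	common	1.97	4.74	0.72	0.38	7.81
Rd+VCd+D+Pd	common	4.13	0.95	0.71	0.38	6.17
Rd+VCd+Pd+D	common	4.13	0.95	0.46	0.59	6.13
DRd+PVd+Kd+Vd	optimal	7.48	1.29	0.71	0.28	9.76
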