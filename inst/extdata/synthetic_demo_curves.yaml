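# Synthetic demonstration curve library (illustrative parameter values only;
# not derived from any trial). One PFS record per regimen/setting; Rd in the
# newly-diagnosed setting is a direct curve and DVMP is derived from it via
# a hazard ratio, demonstrating reference resolution.
- regimen: DRd
  line_setting: newly_diagnosed
  endpoint: PFS
  family: weibull
  params: {shape: 1.2, scale: 7.0}
- regimen: Rd
  line_setting: newly_diagnosed
  endpoint: PFS
  family: exponential
  params: {rate: 0.28}
- regimen: VMP
  line_setting: newly_diagnosed
  endpoint: PFS
  family: exponential
  params: {rate: 0.45}
- regimen: DVMP
  line_setting: newly_diagnosed
  endpoint: PFS
  reference: Rd
  hr: 0.55
- regimen: PVd
  line_setting: relapsed_refractory
  endpoint: PFS
  family: exponential
  params: {rate: 0.85}
- regimen: DRd
  line_setting: relapsed_refractory
  endpoint: PFS
  family: exponential
  params: {rate: 0.32}
- regimen: Kd
  line_setting: relapsed_refractory
  endpoint: PFS
  family: exponential
  params: {rate: 1.4}
- regimen: Vd
  line_setting: relapsed_refractory
  endpoint: PFS
  family: exponential
  params: {rate: 2.2}
- regimen: VCd
  line_setting: relapsed_refractory
  endpoint: PFS
  family: exponential
  params: {rate: 1.6}
- regimen: Pd
  line_setting: double_refractory
  endpoint: PFS
  family: exponential
  params: {rate: 2.4}
- regimen: D
  line_setting: double_refractory
  endpoint: PFS
  family: exponential
  params: {rate: 2.6}
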