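# dog_T2: single 50 mg intramuscular dose, 0.5 mL depot
name: dog_T2
dose: {value: 50, unit: mg}
depot_volume: {value: 0.5, unit: mL}
molar_conversion_factor: 1.0
physchem:
  solubility: {value: 0.00704, unit: mg/mL}
  solid_density: {value: 1.2, unit: g/cm^3}
  diffusion_coeff: {value: 4.69e-12, unit: m^2/s}
  diffusion_layer: {value: 3, unit: um}
disposition:
  vd: {value: 8.5, unit: L}
  ke: {value: 0.0912, unit: 1/h}  # 0.693 / 7.6 h half-life = 0.0912 1/h
  cl_perf: {value: 35, unit: mL/h}  # perfusion clearance of the depot region
  bioavailability: 0.72
bins:
  mass_fraction: [0.02, 0.03, 0.05, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10]
  mean_diameter_um: [0.547, 1.10, 1.46, 1.96, 2.60, 3.24, 3.94, 4.76, 5.77, 7.14, 9.29, 13.9]
  lag_time_h: [4.8, 19.2, 28.8, 48.0, 64.8, 84.0, 96.0, 96.0, 120.0, 120.0, 120.0, 120.0]
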