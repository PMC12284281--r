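# dog_R: single 50 mg intramuscular dose, 0.5 mL depot
name: dog_R
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
  bioavailability: 1.0
bins:
  mass_fraction: [0.02, 0.03, 0.05, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10]
  mean_diameter_um: [0.584, 1.24, 1.66, 2.25, 3.03, 3.81, 4.67, 5.68, 6.94, 8.66, 11.4, 17.1]
  lag_time_h: [4.8, 21.6, 33.6, 52.8, 79.2, 84.0, 84.0, 72.0, 72.0, 72.0, 72.0, 72.0]
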