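# human_T1: single 50 mg intramuscular dose, 0.5 mL depot
name: human_T1
dose: {value: 50, unit: mg}
depot_volume: {value: 0.5, unit: mL}
molar_conversion_factor: 1.0
physchem:
  solubility: {value: 0.00704, unit: mg/mL}
  solid_density: {value: 1.2, unit: g/cm^3}
  diffusion_coeff: {value: 9.78e-13, unit: m^2/s}
  diffusion_layer: {value: 3, unit: um}
disposition:
  vd: {value: 391, unit: L}
  ke: {value: 0.01266, unit: 1/h}  # CL/Vd = 4.95/391 = 0.012660 1/h
  cl_perf: {value: 7.3, unit: mL/h}  # perfusion clearance of the depot region
  bioavailability: 0.83
bins:
  mass_fraction: [0.02, 0.03, 0.05, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10]
  mean_diameter_um: [0.592, 1.18, 1.56, 2.08, 2.75, 3.42, 4.14, 4.98, 6.03, 7.45, 9.65, 14.4]
  lag_time_h: [1.2, 4.8, 12.0, 19.2, 28.8, 60.0, 72.0, 72.0, 72.0, 72.0, 144.0, 144.0]
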