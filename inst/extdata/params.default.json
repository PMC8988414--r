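{
  "hemodynamics": {
    "viscosity_poise": 0.037,
    "mean_aortic_pressure_dyn_cm2": 133322,
    "cardiac_period_s": 0.8,
    "total_input_flow_cc_s": 8.33,
    "material_area_compliance_mm2_mmHg": 0.0975,
    "compliance_mode": "per_segment"
  },
  "activity_states": {
    "R":  { "LAD": 250000, "LCX": 250000, "RCA": 250000 },
    "E1": { "LAD": 120000, "LCX": 120000, "RCA": 120000 },
    "E2": { "LAD": 60000,  "LCX": 60000,  "RCA": 60000 }
  },
  "chamber": {
    "inherent_resistance_dyn_s_cm5": { "LAD": 1671, "LCX": 1820, "RCA": 591 },
    "P0_mmHg": 760,
    "V0_mm3": 44000,
    "Ps_mmHg": 120,
    "Pd_mmHg": 80
  }
}
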