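{
  "metadata": {
    "source": "tabulated tissue properties of a rodent head/body finite-element model",
    "units": {
      "shear_moduli": "kPa",
      "beta": "1/ms",
      "elastic_moduli": "MPa",
      "bulk_moduli": "GPa",
      "density": "kg/m^3"
    },
    "notes": "Densities are conventional stand-ins; they are not part of the tabulated data."
  },
  "materials": [
    {
      "type": "kelvin_maxwell",
      "name": "gray cortex",
      "G0_kPa": 5.16,
      "Ginf_kPa": 1.54,
      "beta_per_ms": 0.05,
      "K_GPa": 2,
      "density_kg_m3": 1040,
      "brain": true
    },
    {
      "type": "kelvin_maxwell",
      "name": "hippocampus",
      "G0_kPa": 10.32,
      "Ginf_kPa": 3.08,
      "beta_per_ms": 0.05,
      "K_GPa": 2,
      "density_kg_m3": 1040,
      "brain": true
    },
    {
      "type": "kelvin_maxwell",
      "name": "cerebellum",
      "G0_kPa": 4.64,
      "Ginf_kPa": 1.38,
      "beta_per_ms": 0.05,
      "K_GPa": 2,
      "density_kg_m3": 1040,
      "brain": true
    },
    {
      "type": "kelvin_maxwell",
      "name": "pia-arachnoid",
      "G0_kPa": 1379,
      "Ginf_kPa": 153,
      "beta_per_ms": 0.04,
      "density_kg_m3": 1130,
      "brain": false
    },
    {
      "type": "kelvin_maxwell",
      "name": "intervertebral disc",
      "G0_kPa": 1000,
      "Ginf_kPa": 100,
      "beta_per_ms": 0.05,
      "density_kg_m3": 1100,
      "brain": false
    },
    {
      "type": "linear_elastic",
      "name": "dura mater",
      "E_MPa": 31.5,
      "nu": 0.45,
      "density_kg_m3": 1130
    },
    {
      "type": "linear_elastic",
      "name": "skull, diploe layer",
      "E_MPa": 600,
      "nu": 0.3,
      "density_kg_m3": 1300
    },
    {
      "type": "linear_elastic",
      "name": "skull, cortical layer",
      "E_MPa": 15000,
      "nu": 0.3,
      "density_kg_m3": 1800
    },
    {
      "type": "linear_elastic",
      "name": "vertebral body",
      "E_MPa": 7000,
      "nu": 0.3,
      "density_kg_m3": 1800
    }
  ]
}
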