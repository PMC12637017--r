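{
  "comment": "Default material set: compositions (number fractions) and densities for vitreous ice, protein and nucleic acid, together with the 200 keV averaged low-angle elastic scattering factors, >6 mrad absorption coefficients (1/Angstrom) and measured mean free paths (nm) used for multislice contrast work.",
  "mfp_energy_keV": 200,
  "materials": [
    {
      "name": "ice",
      "fractions": {"O": 0.3333333333333333, "H": 0.6666666666666667},
      "density": 0.9,
      "avg_f0": 0.8885,
      "mu_abs": 1.82e-4,
      "elastic_mfp": 581,
      "inelastic_mfp": 157
    },
    {
      "name": "protein",
      "fractions": {"C": 0.31, "N": 0.08, "O": 0.08, "H": 0.525, "S": 0.005},
      "density": 1.3,
      "avg_f0": 1.5170,
      "mu_abs": 2.71e-4,
      "elastic_mfp": 342,
      "inelastic_mfp": 92.3
    },
    {
      "name": "dna",
      "fractions": {"C": 0.24, "N": 0.09, "O": 0.14, "H": 0.51, "P": 0.02},
      "density": 1.7,
      "avg_f0": 1.5808,
      "mu_abs": 3.62e-4,
      "elastic_mfp": 256,
      "inelastic_mfp": 69.1
    },
    {
      "name": "vacuum",
      "fractions": {"H": 1.0},
      "density": 0.0
    }
  ]
}
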