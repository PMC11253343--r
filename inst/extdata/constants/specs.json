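{
  "source": "SPECS",
  "citation": "Representative association constants (log10, molar, 20 C, 100 mM ionic equivalence) in the style of the SPECS program lineage (Fabiato & Fabiato). Illustrative transcription, not an authoritative copy of any single table.",
  "metals": [
    { "id": "Ca", "charge": 2 },
    { "id": "Mg", "charge": 2 }
  ],
  "ligands": [
    {
      "id": "EGTA",
      "charge": -4,
      "ref_temperature_c": 20,
      "ref_ionic_equivalence_mm": 100,
      "protonation": [
        { "step": 1, "log_k": 9.43, "delta_h_kj_mol": -23.4 },
        { "step": 2, "log_k": 8.8, "delta_h_kj_mol": -24.3 },
        { "step": 3, "log_k": 2.65, "delta_h_kj_mol": null },
        { "step": 4, "log_k": 2, "delta_h_kj_mol": null }
      ],
      "complexes": [
        { "metal": "Ca", "protons": 0, "log_k": 10.72, "delta_h_kj_mol": -33.4 },
        { "metal": "Ca", "protons": 1, "log_k": 5.25, "delta_h_kj_mol": null },
        { "metal": "Mg", "protons": 0, "log_k": 5.17, "delta_h_kj_mol": 21.3 },
        { "metal": "Mg", "protons": 1, "log_k": 3.35, "delta_h_kj_mol": null }
      ]
    },
    {
      "id": "EDTA",
      "charge": -4,
      "ref_temperature_c": 20,
      "ref_ionic_equivalence_mm": 100,
      "protonation": [
        { "step": 1, "log_k": 10.26, "delta_h_kj_mol": -23.4 },
        { "step": 2, "log_k": 6.16, "delta_h_kj_mol": -17.6 },
        { "step": 3, "log_k": 2.67, "delta_h_kj_mol": null },
        { "step": 4, "log_k": 2, "delta_h_kj_mol": null }
      ],
      "complexes": [
        { "metal": "Ca", "protons": 0, "log_k": 10.59, "delta_h_kj_mol": -27 },
        { "metal": "Ca", "protons": 1, "log_k": 3.5, "delta_h_kj_mol": null },
        { "metal": "Mg", "protons": 0, "log_k": 8.65, "delta_h_kj_mol": 13.8 },
        { "metal": "Mg", "protons": 1, "log_k": 2.26, "delta_h_kj_mol": null }
      ]
    },
    {
      "id": "ATP",
      "charge": -4,
      "ref_temperature_c": 20,
      "ref_ionic_equivalence_mm": 100,
      "protonation": [
        { "step": 1, "log_k": 6.5, "delta_h_kj_mol": -5 },
        { "step": 2, "log_k": 4, "delta_h_kj_mol": -2.1 }
      ],
      "complexes": [
        { "metal": "Ca", "protons": 0, "log_k": 3.82, "delta_h_kj_mol": 2 },
        { "metal": "Ca", "protons": 1, "log_k": 1.9, "delta_h_kj_mol": null },
        { "metal": "Mg", "protons": 0, "log_k": 4.2, "delta_h_kj_mol": 18 },
        { "metal": "Mg", "protons": 1, "log_k": 2.3, "delta_h_kj_mol": null }
      ]
    }
  ]
}
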