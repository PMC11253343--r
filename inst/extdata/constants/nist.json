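{
  "source": "NIST",
  "citation": "Representative critically-selected association constants (log10, molar, 20 C, 100 mM ionic equivalence) compiled from the critical stability-constant literature for the NIST lineage. Illustrative transcription, not an authoritative copy of any single table.",
  "metals": [
    { "id": "Ca", "charge": 2 },
    { "id": "Mg", "charge": 2 },
    { "id": "Zn", "charge": 2 }
  ],
  "ligands": [
    {
      "id": "EGTA",
      "charge": -4,
      "ref_temperature_c": 20,
      "ref_ionic_equivalence_mm": 100,
      "protonation": [
        { "step": 1, "log_k": 9.4, "delta_h_kj_mol": -23.4 },
        { "step": 2, "log_k": 8.79, "delta_h_kj_mol": -24.3 },
        { "step": 3, "log_k": 2.66, "delta_h_kj_mol": null },
        { "step": 4, "log_k": 2, "delta_h_kj_mol": null }
      ],
      "complexes": [
        { "metal": "Ca", "protons": 0, "log_k": 10.86, "delta_h_kj_mol": -33.4 },
        { "metal": "Ca", "protons": 1, "log_k": 5.33, "delta_h_kj_mol": null },
        { "metal": "Mg", "protons": 0, "log_k": 5.28, "delta_h_kj_mol": 21.3 },
        { "metal": "Mg", "protons": 1, "log_k": 3.37, "delta_h_kj_mol": null },
        { "metal": "Zn", "protons": 0, "log_k": 12.6, "delta_h_kj_mol": -24.3 }
      ]
    },
    {
      "id": "EDTA",
      "charge": -4,
      "ref_temperature_c": 20,
      "ref_ionic_equivalence_mm": 100,
      "protonation": [
        { "step": 1, "log_k": 10.17, "delta_h_kj_mol": -23.4 },
        { "step": 2, "log_k": 6.11, "delta_h_kj_mol": -17.6 },
        { "step": 3, "log_k": 2.68, "delta_h_kj_mol": null },
        { "step": 4, "log_k": 2, "delta_h_kj_mol": null }
      ],
      "complexes": [
        { "metal": "Ca", "protons": 0, "log_k": 10.61, "delta_h_kj_mol": -27 },
        { "metal": "Ca", "protons": 1, "log_k": 3.52, "delta_h_kj_mol": null },
        { "metal": "Mg", "protons": 0, "log_k": 8.83, "delta_h_kj_mol": 13.8 },
        { "metal": "Mg", "protons": 1, "log_k": 2.28, "delta_h_kj_mol": null },
        { "metal": "Zn", "protons": 0, "log_k": 16.5, "delta_h_kj_mol": -20.1 }
      ]
    },
    {
      "id": "ATP",
      "charge": -4,
      "ref_temperature_c": 20,
      "ref_ionic_equivalence_mm": 100,
      "protonation": [
        { "step": 1, "log_k": 6.48, "delta_h_kj_mol": -5 },
        { "step": 2, "log_k": 4, "delta_h_kj_mol": -2.1 }
      ],
      "complexes": [
        { "metal": "Ca", "protons": 0, "log_k": 3.91, "delta_h_kj_mol": 2 },
        { "metal": "Ca", "protons": 1, "log_k": 1.95, "delta_h_kj_mol": null },
        { "metal": "Mg", "protons": 0, "log_k": 4.29, "delta_h_kj_mol": 18 },
        { "metal": "Mg", "protons": 1, "log_k": 2.35, "delta_h_kj_mol": null }
      ]
    }
  ]
}
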