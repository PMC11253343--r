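{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "chelation constant-set interchange format",
  "description": "A named library of metal and ligand stability constants. Conventions: all log_k are stepwise ASSOCIATION constants, log10, molar basis, valid at the ligand record's reference temperature (Celsius) and ionic equivalence (mM). Protonation step 1 is the first proton onto the fully deprotonated ligand, so step 1 carries the highest pK; steps must be consecutive from 1 (at most 4). A complex with protons = p is formed from free metal plus the p-fold protonated ligand form (protons = 1 means M + HL <=> MHL). delta_h_kj_mol is the standard enthalpy of the association reaction (kJ/mol, exothermic negative); null or absent means the constant receives no temperature correction. Unknown extra keys are preserved on round trip but ignored by computation.",
  "type": "object",
  "required": ["metals", "ligands"],
  "properties": {
    "source": { "type": "string" },
    "citation": { "type": "string" },
    "metals": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "charge"],
        "properties": {
          "id": { "type": "string" },
          "charge": { "type": "integer", "minimum": 1, "maximum": 3 }
        }
      }
    },
    "ligands": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "charge", "ref_temperature_c", "ref_ionic_equivalence_mm"],
        "properties": {
          "id": { "type": "string" },
          "charge": { "type": "integer" },
          "ref_temperature_c": { "type": "number" },
          "ref_ionic_equivalence_mm": { "type": "number" },
          "protonation": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["step", "log_k"],
              "properties": {
                "step": { "type": "integer", "minimum": 1, "maximum": 4 },
                "log_k": { "type": "number" },
                "delta_h_kj_mol": { "type": ["number", "null"] }
              }
            }
          },
          "complexes": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["metal", "protons", "log_k"],
              "properties": {
                "metal": { "type": "string" },
                "protons": { "type": "integer", "minimum": 0 },
                "log_k": { "type": "number" },
                "delta_h_kj_mol": { "type": ["number", "null"] }
              }
            }
          }
        }
      }
    }
  }
}
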