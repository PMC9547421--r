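{
  "comment": "Curated IUPAC patterns in the style of PLACE/PlantCARE entries. These are editable inputs, not fixed biological truth; provenance per entry.",
  "motifs": [
    {"name": "ABRE",       "category": "hormone",     "pattern": "TACGTG",     "provenance": "PlantCARE-style ABA-responsive element"},
    {"name": "TGA-element","category": "hormone",     "pattern": "AACGAC",     "provenance": "PlantCARE-style auxin-responsive element"},
    {"name": "DRE",        "category": "stress",      "pattern": "RCCGAC",     "provenance": "PLACE-style dehydration-responsive element"},
    {"name": "MBS",        "category": "stress",      "pattern": "CAACTG",     "provenance": "PlantCARE-style MYB binding site"},
    {"name": "LTR",        "category": "stress",      "pattern": "CCGAAA",     "provenance": "PlantCARE-style low-temperature-responsive element"},
    {"name": "TC-rich",    "category": "stress",      "pattern": "GTTTTCTTAC", "provenance": "PlantCARE-style defense/stress element"},
    {"name": "WUN-motif",  "category": "stress",      "pattern": "AAATTTCCT",  "provenance": "PlantCARE-style wound-responsive element"},
    {"name": "RY-element", "category": "development", "pattern": "CATGCATG",   "provenance": "PlantCARE-style seed-specific element"},
    {"name": "G-box",      "category": "light",       "pattern": "CACGTG",     "provenance": "PlantCARE-style light-responsive element"},
    {"name": "ARE",        "category": "other",       "pattern": "AAACCA",     "provenance": "PlantCARE-style anaerobic-induction element"},
    {"name": "Sp1",        "category": "light",       "pattern": "GGGCGG",     "provenance": "PlantCARE-style light-responsive element"}
  ]
}
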