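# Substitution policy calibrated for the 37-residue Amylin monomer.
# Position-specific overrides carry the curated target choices; the defaults
# cover any other site a rule selects. Targets are quoted so single-letter
# codes are never YAML-coerced to booleans.
provenance: amylin_2015 bundled policy
defaults:
  core_charged:
    default: "E"
  surface_hydrophobic:
    default: "M"
  strand_charged:
    default: "E"
overrides:
  2: "Q"
  3: "H"
  4: "S"
  6: "M"
  7: "T"
  8: "E"
  9: "N"
  10: "H"
  12: "E"
  13: "R"
  15: "D"
  16: "D"
  17: "E"
  23: "E"
  24: "D"
  25: "R"
  26: "R"
  27: "R"
  32: "K"
  33: "E"
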