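{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "coalunits pipeline report",
  "type": "object",
  "required": ["config", "nuclear", "units"],
  "properties": {
    "config": {
      "type": "object",
      "required": ["seed", "n_perm", "alpha"],
      "properties": {
        "seed": {"type": "integer"},
        "n_perm": {"type": "integer", "minimum": 0},
        "alpha": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1},
        "generation_length": {"type": "number", "exclusiveMinimum": 0}
      }
    },
    "nuclear": {
      "type": "object",
      "required": ["fst", "fst_prime", "rst", "amova_pct_among"],
      "properties": {
        "n_ind": {"type": "integer"},
        "n_loci": {"type": "integer"},
        "fst": {"type": "number"},
        "fst_max": {"type": "number"},
        "fst_prime": {"type": ["number", "null"]},
        "amova_pct_among": {"type": "number"},
        "amova_p": {"type": "number"},
        "rst": {"type": "number"},
        "p_rst": {"type": "number"},
        "rst_p": {"type": "number"}
      }
    },
    "plastid": {
      "type": ["object", "null"],
      "properties": {
        "n_seq": {"type": "integer"},
        "H": {"type": "integer"},
        "hap_diversity": {"type": "number"},
        "nucleotide_diversity": {"type": "number"},
        "tajima_D": {"type": ["number", "null"]},
        "phi_st": {"type": "number"},
        "phi_st_prime": {"type": ["number", "null"]},
        "spatially_segregated": {"type": "boolean"}
      }
    },
    "abc": {"type": ["object", "null"]},
    "units": {
      "type": "object",
      "required": ["n_ESU", "n_MU"],
      "properties": {
        "n_ESU": {"type": "integer", "minimum": 1},
        "n_MU": {"type": "integer", "minimum": 1},
        "rationale": {"type": "array", "items": {"type": "string"}}
      }
    }
  }
}
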