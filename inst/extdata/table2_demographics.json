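{
  "n_reference": 47,
  "sex": { "male": 0.2978723, "female": 0.7021277 },
  "education": {
    "secondary school": 0.1489362,
    "high school": 0.0851064,
    "university": 0.7659574
  },
  "family_situation": {
    "has_dependant_child": 0.1489362,
    "has_adult_non_self-sufficient_dependant": 0.0425532,
    "none_of_the_above": 0.8085106
  },
  "profession": {
    "healthcare professional": 0.70,
    "commercial activities": 0.10,
    "unemployed": 0.08,
    "other": 0.12
  },
  "marital_status": {
    "married": 0.45,
    "single": 0.40,
    "other": 0.15
  },
  "age": { "mean": 40.8, "sd": 14.79, "min": 21, "max": 68 }
}
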