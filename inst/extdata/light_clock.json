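{
  "schema": "bioclock/clock/v1",
  "provenance": "light",
  "beta1": null,
  "constant": -13.5298,
  "coefficients": {
    "creatinine": 8.3313,
    "glucose": 0.827,
    "log_crp": 5.7305
  },
  "reference_values": null,
  "units_note": "Units as published: no conversion is applied. Conventionally creatinine mg/dL, glucose mmol/L, CRP mg/L (natural log applied to CRP)."
}
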