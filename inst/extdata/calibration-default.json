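{
  "model": {
    "MW": {
      "slope": 0.972713724228534,
      "intercept": 1.45097135547308,
      "pcc": 0.999957066987669
    },
    "HBA": {
      "slope": 1,
      "intercept": -8.34887714518118e-16,
      "pcc": 1
    },
    "HBD": {
      "slope": 0.511111111111111,
      "intercept": 0.146666666666667,
      "pcc": 0.667297681163508
    },
    "logP": {
      "slope": 0.797318458177999,
      "intercept": 0.156389516470363,
      "pcc": 0.9593411551002
    }
  },
  "n": 25
}
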