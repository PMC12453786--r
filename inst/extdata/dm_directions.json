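{
  "Precision": "benefit",
  "Recall": "benefit",
  "Fscore": "benefit",
  "Kappa": "benefit",
  "HammingLoss": "cost",
  "MCC": "benefit",
  "Accuracy": "benefit"
}
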