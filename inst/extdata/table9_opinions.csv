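Model,Precision,Accuracy
SVM,D,D
KNN,BD,BD
DT,ND,ND
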