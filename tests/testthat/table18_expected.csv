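Model,score_e1,rank_e1,score_e2,rank_e2,score_e3,rank_e3,final_score,final_rank
XGBoost,0.2286,4,0.181,3,0.2048,4,0.2048,4
KNN,0.6595,10,0.5738,10,0.6881,11,0.6405,10
DT,0.3071,6,0.2524,6,0.2762,6,0.2786,6
RF,0.1571,2,0.1571,2,0.1571,2,0.1571,2
SVM,0.5429,9,0.4548,9,0.5119,9,0.5032,9
ANN,0.3357,7,0.2762,7,0.3071,7,0.3063,7
SGD,0.4857,8,0.3929,8,0.4238,8,0.4341,8
GBoost,0.1333,1,0.1333,1,0.1333,1,0.1333,1
LGBM,0.2048,3,0.2048,4,0.181,3,0.1969,3
AdaBoost,0.8833,12,0.8833,12,0.8833,12,0.8833,12
NB,0.6881,11,0.6286,11,0.6595,10,0.6587,11
ET,0.2595,5,0.2286,5,0.2286,5,0.2389,5
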