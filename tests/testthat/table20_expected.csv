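Model,Precision_AD,Precision_PD,Recall_AD,Recall_PD,Fscore_AD,Fscore_PD,Kappa_AD,Kappa_PD,HammingLoss_AD,HammingLoss_PD,MCC_AD,MCC_PD,Accuracy_AD,Accuracy_PD
XGBoost,3.304,3.97,5.192,6.41,4.458,5.45,4.936,6.27,-3.892,-21.91,4.914,6.24,3.892,4.73
KNN,9.468,15.14,9.107,14.69,8.877,14.37,7.099,12.07,-5.554,-16.20,7.490,12.70,5.554,8.45
DT,4.785,6.07,4.746,6.02,4.792,6.08,4.321,5.72,-3.375,-16.52,4.314,5.71,3.375,4.24
RF,0.203,0.24,5.050,6.27,3.317,4.03,2.891,3.61,-2.136,-12.97,2.886,3.59,2.136,2.56
SVM,12.333,19.64,9.101,14.08,9.780,15.40,3.749,5.70,-2.610,-9.21,4.027,6.10,2.610,3.64
ANN,5.358,6.87,5.361,6.98,4.924,6.37,2.870,3.80,-2.149,-10.54,3.155,4.18,2.149,2.70
SGD,2.202,3.06,-1.956,-2.75,-2.641,-3.85,-3.728,-5.60,3.296,11.81,-3.348,-4.94,-3.296,-4.57
GBoost,0.803,0.93,4.744,5.78,3.259,3.90,3.846,4.77,-2.967,-18.45,3.844,4.76,2.967,3.54
LGBM,2.755,3.30,4.565,5.61,3.819,4.65,4.391,5.55,-3.291,-19.04,4.327,5.46,3.291,3.98
AdaBoost,3.539,4.45,5.046,6.48,4.546,5.80,4.275,5.68,-3.613,-17.44,4.157,5.51,3.613,4.56
NB,4.117,6.17,5.143,7.88,4.723,7.17,5.359,8.49,-4.490,-12.93,5.405,8.55,4.490,6.88
ET,-0.179,-0.21,2.689,3.22,1.355,1.59,2.895,3.49,-1.964,-11.83,2.805,3.38,1.964,2.36
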