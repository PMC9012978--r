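model,class,sensitivity,specificity,ppv,npv,precision,prevalence,balanced_accuracy
kmeans,B,0.828,0.732,0.447,0.942,0.447,0.207,0.780
kmeans,T,0.763,0.771,0.604,0.876,0.604,0.314,0.767
kmeans,TB,0.305,0.860,0.667,0.575,0.667,0.478,0.583
kmeans,mu,0.632,0.788,0.573,0.798,0.573,0.333,0.710
pam,B,0.738,0.740,0.498,0.889,0.498,0.259,0.739
pam,T,0.658,0.805,0.722,0.753,0.722,0.436,0.731
pam,TB,0.229,0.786,0.319,0.699,0.319,0.305,0.507
pam,mu,0.541,0.777,0.513,0.780,0.513,0.333,0.659
rf,B,0.779,0.951,0.931,0.835,0.931,0.460,0.865
rf,T,0.803,0.910,0.859,0.871,0.859,0.406,0.856
rf,TB,0.600,0.821,0.341,0.930,0.341,0.134,0.711
rf,mu,0.727,0.894,0.710,0.879,0.710,0.333,0.811
nb,B,0.817,0.779,0.582,0.918,0.582,0.274,0.798
nb,T,0.727,0.850,0.784,0.806,0.784,0.428,0.789
nb,TB,0.364,0.843,0.496,0.757,0.496,0.298,0.604
nb,mu,0.636,0.824,0.621,0.827,0.621,0.333,0.730
mlp_classic,B,0.194,0.957,0.737,0.655,0.737,0.385,0.575
mlp_classic,T,0.296,0.543,0.284,0.558,0.284,0.38,0.419
mlp_classic,TB,0.591,0.524,0.277,0.806,0.277,0.235,0.558
mlp_classic,mu,0.36,0.675,0.432,0.673,0.432,0.333,0.518
mlp_modern,B,0.917,0.757,0.702,0.935,0.702,0.385,0.837
mlp_modern,T,0.761,0.871,0.783,0.856,0.783,0.38,0.816
mlp_modern,TB,0.295,0.923,0.542,0.81,0.542,0.235,0.609
mlp_modern,mu,0.658,0.85,0.675,0.867,0.675,0.333,0.754
mlp_modern_aug,B,0.969,0.952,0.930,0.979,0.930,0.398,0.960
mlp_modern_aug,T,0.931,0.968,0.950,0.956,0.950,0.392,0.950
mlp_modern_aug,TB,0.841,0.969,0.878,0.958,0.878,0.210,0.905
mlp_modern_aug,mu,0.914,0.963,0.919,0.964,0.919,0.333,0.938
rf_aug,B,0.963,0.981,0.971,0.975,0.971,0.402,0.972
rf_aug,T,0.946,0.970,0.953,0.965,0.953,0.395,0.958
rf_aug,TB,0.912,0.969,0.884,0.977,0.884,0.203,0.941
rf_aug,mu,0.94,0.973,0.936,0.972,0.936,0.333,0.957
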