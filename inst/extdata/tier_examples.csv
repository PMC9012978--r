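image_id,true_class,prob_B,prob_T,prob_TB,max_prob,predicted_class,correct,tier,consistent
Root001,TB,0.340,0.325,0.335,0.340,B,No,LLL,yes
Root002,TB,0.346,0.335,0.319,0.346,B,No,LLL,yes
Root003,B,0.328,0.355,0.317,0.355,T,No,LLL,yes
Root004,B,0.351,0.288,0.361,0.361,TB,No,LLL,yes
Root005,B,0.362,0.282,0.356,0.362,B,Yes,LLL,yes
Root006,TB,0.296,0.362,0.342,0.362,T,No,LLL,yes
Root007,T,0.368,0.283,0.349,0.367,B,No,LLL,no
Root008,B,0.502,0.234,0.263,0.502,B,Yes,LL,yes
Root009,B,0.503,0.237,0.260,0.503,B,Yes,LL,yes
Root010,TB,0.508,0.286,0.206,0.508,B,No,LL,yes
Root011,T,0.175,0.317,0.508,0.508,TB,No,LL,yes
Root012,T,0.229,0.508,0.263,0.508,T,Yes,LL,yes
Root013,T,0.130,0.362,0.509,0.508,TB,No,LL,no
Root014,B,0.820,0.041,0.139,0.820,B,Yes,HH,yes
Root015,TB,0.820,0.071,0.109,0.820,B,No,HH,yes
Root016,T,0.005,0.990,0.005,0.990,T,Yes,HHH,yes
Root017,B,0.994,0.000,0.006,0.994,B,Yes,HHH,yes
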