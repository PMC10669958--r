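observer,arm,TP,TN,FP,FN,sensitivity,specificity,accuracy,kappa
Observer 1,unaided,4377,13671,257,1631,0.729,0.982,0.905,0.759
Observer 1,aided,5248,13465,463,760,0.874,0.967,0.939,0.852
Observer 2,unaided,4609,13357,571,1399,0.767,0.959,0.901,0.756
Observer 2,aided,5210,13455,473,798,0.867,0.966,0.936,0.846
Observer 3,unaided,4588,10184,3744,1420,0.764,0.731,0.741,0.446
Observer 3,aided,5299,12875,1053,709,0.882,0.924,0.912,0.793
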