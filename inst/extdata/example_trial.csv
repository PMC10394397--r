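block,arm,response
0,0,0.214
0,0,0.48
0,1,0.088
0,1,0.444
0,2,-0.363
0,2,0.123
1,1,-0.864
1,1,0.49
1,2,-0.364
1,1,-1.294
1,0,-0.746
1,0,0.922
1,0,0.75
2,1,-2.509
2,2,-3.041
2,1,0
2,1,-0.394
2,0,-1.745
2,0,0.499
2,0,0.271
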