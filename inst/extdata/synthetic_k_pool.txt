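4.591915
2.254901
5.972224
5.707028
8.980131
1.595014
3.668532
2.288095
3.180194
5.825454
6.377770
8.408379
0.747120
0.780638
3.205630
5.883020
3.114469
2.350826
4.143799
5.605465
2.472425
4.687418
5.143360
3.522491
3.132385
5.515580
6.837505
6.392320
0.482249
1.850083
3.706203
2.414409
1.230164
2.665907
2.691806
5.206388
4.006089
4.561618
3.239690
4.007909
4.655422
4.806152
5.729855
1.191670
5.574927
9.291805
0.841703
3.870645
1.666857
5.741572
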