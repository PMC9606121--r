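E_MeV,S_MeV_per_um
0.01,0.048056515
0.010444026,0.048951833
0.010907767,0.049864341
0.0113921,0.050794899
0.011897938,0.051744418
0.012426237,0.052713854
0.012977993,0.053704215
0.013554249,0.054716559
0.014156093,0.055752003
0.014784659,0.05681172
0.015441136,0.057896943
0.016126762,0.059008972
0.016842831,0.060149173
0.017590696,0.061318982
0.018371768,0.062519912
0.019187521,0.063753553
0.020039496,0.065021581
0.020929301,0.066325759
0.021858615,0.067667942
0.022829193,0.069050087
0.023842868,0.070474254
0.024901552,0.071942614
0.026007244,0.073457056
0.027162032,0.075017422
0.028368096,0.076622749
0.029627712,0.078271916
0.030943258,0.079963631
0.032317218,0.081696417
0.033752185,0.083468603
0.035250868,0.085278306
0.036816096,0.087123426
0.038450825,0.089001624
0.04015814,0.090910323
0.041941263,0.092846685
0.043803563,0.09480761
0.045748553,0.096789724
0.047779905,0.098789372
0.049901455,0.10080261
0.052117207,0.10282586
0.054431344,0.10485836
0.056848234,0.10690026
0.059372441,0.10895177
0.062008729,0.11101314
0.064762075,0.11308472
0.067637676,0.1151669
0.070640962,0.11726015
0.073777601,0.11936501
0.077053515,0.12148209
0.080474887,0.12361209
0.084048178,0.12575575
0.087780131,0.12791392
0.091677793,0.13008752
0.095748521,0.13227754
0.1,0.13448505
0.10444026,0.13671114
0.10907767,0.13895655
0.113921,0.14122201
0.11897938,0.14350829
0.12426237,0.14581621
0.12977993,0.14814666
0.13554249,0.15050056
0.14156093,0.1528789
0.14784659,0.15528274
0.15441136,0.15771318
0.16126762,0.16017139
0.16842831,0.1626586
0.17590696,0.1651761
0.18371768,0.16772527
0.19187521,0.17030754
0.20039496,0.17292441
0.20929301,0.17557432
0.21858615,0.17824455
0.22829193,0.18091909
0.23842868,0.18358103
0.24901552,0.18621249
0.26007244,0.18879469
0.27162032,0.19130796
0.28368096,0.19373182
0.29627712,0.19604505
0.30943258,0.19822797
0.32317218,0.20028235
0.33752185,0.20222307
0.35250868,0.2040661
0.36816096,0.20582829
0.38450825,0.20752728
0.4015814,0.20918144
0.41941263,0.21080072
0.43803563,0.2123676
0.45748553,0.21385876
0.47779905,0.21525033
0.49901455,0.21651799
0.52117207,0.21764088
0.54431344,0.21861551
0.56848234,0.2194437
0.59372441,0.22012764
0.62008729,0.2206663
0.64762075,0.22102901
0.67637676,0.22117019
0.70640962,0.22104469
0.73777601,0.22062208
0.77053515,0.21990312
0.80474887,0.21889366
0.84048178,0.21760674
0.87780131,0.2160724
0.91677793,0.21432282
0.95748521,0.2123664
1,0.21018358
1.0444026,0.20776109
1.0907767,0.20511212
1.13921,0.20225646
1.1897938,0.19921395
1.2426237,0.1960043
1.2977993,0.19265014
1.3554249,0.18919209
1.4156093,0.18567547
1.4784659,0.18214281
1.5441136,0.17862919
1.6126762,0.1751153
1.6842831,0.17155074
1.7590696,0.16788899
1.8371768,0.16411627
1.9187521,0.16029831
2.0039496,0.15650879
2.0929301,0.15279924
2.1858615,0.14916324
2.2829193,0.14558351
2.3842868,0.14204436
2.4901552,0.13853158
2.6007244,0.13503399
2.7162032,0.13154948
2.8368096,0.1280789
2.9627712,0.12462326
3.0943258,0.12118753
3.2317218,0.11781282
3.3752185,0.11455607
3.5250868,0.11146798
3.6816096,0.10855586
3.8450825,0.10573533
4.015814,0.10291695
4.1941263,0.10004724
4.3803563,0.097157907
4.5748553,0.09429186
4.7779905,0.091468482
4.9901455,0.088679821
5.2117207,0.085932939
5.4431344,0.083304101
5.6848234,0.080853889
5.9372441,0.078424782
6.2008729,0.075814748
6.4762075,0.07316721
6.7637676,0.070737989
7.0640962,0.06862438
7.3777601,0.066764482
7.7053515,0.064882666
8.0474887,0.06282261
8.4048178,0.060601636
8.7780131,0.05841914
9.1677793,0.056472702
9.5748521,0.054801364
10,0.053283108
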