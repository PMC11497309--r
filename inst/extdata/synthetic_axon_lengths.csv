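"condition","replicate_id","length_um"
1.5,1,1679.8
1.5,2,959.4
1.5,3,1469.9
1.5,4,1359.1
1.5,5,1108.7
1.5,6,580.3
3,1,989.6
3,2,895.7
3,3,1331.9
3,4,1084.4
3,5,1109.6
3,6,991.2
7.5,1,1073.5
7.5,2,1071.8
7.5,3,475.7
7.5,4,1858.7
7.5,5,1439.3
7.5,6,1251.8
15,1,784.7
15,2,1324
15,3,927
15,4,981.8
15,5,638.9
15,6,1737.2
30,1,935.7
30,2,1794
30,3,1686.2
30,4,938.9
30,5,1153.1
30,6,1683
75,1,664.8
75,2,848
75,3,731.8
75,4,898.8
75,5,852.7
75,6,1202.6
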