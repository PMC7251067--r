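session,online_positive,offline_positive,true_positives,false_positives,false_negatives,true_negatives
1,3,2,2,1,0,5
2,3,3,3,0,0,5
3,4,2,2,2,0,4
4,8,7,7,1,0,0
5,0,1,0,0,1,7
6,2,2,2,0,0,6
7,1,1,1,0,0,7
8,3,2,2,1,0,5
9,2,2,2,0,0,6
10,2,2,2,0,0,6
11,4,4,4,0,0,4
12,5,4,4,1,0,3
13,2,2,2,0,0,6
14,1,2,1,0,1,6
15,1,0,0,1,0,7
16,1,1,1,0,0,7
17,2,0,0,2,0,6
18,2,2,2,0,0,6
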