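subject,ga_weeks,bw_g,crib,apgar5,sex,cord_ph,duration_h
1,24,670,17,6,M,6.85,55
2,24,740,13,9,F,7.18,48
3,23,540,14,7,F,7.22,49
4,28,1040,7,9,F,7.3,24
5,25,730,12,7,F,7.29,43
6,30,1450,6,5,M,7.02,68
7,26,950,12,6,F,6.96,39
8,31,960,7,9,F,7.23,37
9,25,620,12,6,F,7.34,39
10,26,860,10,8,M,7.12,24
11,26,980,10,8,M,7.24,39
12,30,730,10,10,M,7.32,24
13,24,1240,5,9,F,7.15,24
14,28,1330,4,4,F,7.08,24
15,30,1000,7,10,F,7.24,24
16,28,650,9,7,F,7.22,43
17,28,980,8,8,F,7.16,24
18,28,1060,6,1,M,6.9,83
19,29,1230,7,9,M,7.27,37
20,24,620,13,9,F,7.27,24
21,30,800,10,8,M,7.28,28
22,28,980,8,10,F,7.26,37
23,30,1530,3,8,F,7.1,24
24,23,580,14,6,F,7.24,48
25,28,680,8,8,M,7.32,48
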