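isolate_id,parameter,value
36M,p_mineralization,4.90
36M,iaa,0.98
36M,nitrification,0.99
40M,p_mineralization,4.79
50M,p_mineralization,2.15
50M,iaa,0.98
50M,nitrification,1.99
54M,nitrification,17.88
58M,nitrification,18.41
60M,nitrification,17.56
97M,p_mineralization,8.90
3B,p_mineralization,2.89
3B,iaa,2.96
3B,nitrification,0.40
19B,p_mineralization,1.48
19B,iaa,5.72
19B,nitrification,7.18
6P,nitrification,17.60
20P,nitrification,15.82
23P,p_mineralization,2.17
23P,iaa,3.65
10A,nitrification,18.69
12A,p_mineralization,8.01
12A,iaa,5.82
25A,p_mineralization,3.96
145A,iaa,140.31
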