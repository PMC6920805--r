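isolate_id,parameter,code
36M,p_mineralization,3
36M,iaa,1
36M,nitrification,1
40M,p_mineralization,3
40M,iaa,0
40M,nitrification,0
97M,p_mineralization,3
97M,iaa,0
97M,nitrification,0
54M,p_mineralization,0
54M,iaa,0
54M,nitrification,3
58M,p_mineralization,0
58M,iaa,0
58M,nitrification,3
114M,p_mineralization,0
114M,iaa,3
114M,nitrification,0
3B,p_mineralization,3
3B,iaa,1
3B,nitrification,1
19B,p_mineralization,1
19B,iaa,2
19B,nitrification,3
45B,p_mineralization,0
45B,iaa,3
45B,nitrification,0
89B,p_mineralization,0
89B,iaa,3
89B,nitrification,0
6P,p_mineralization,0
6P,iaa,0
6P,nitrification,3
10A,p_mineralization,0
10A,iaa,0
10A,nitrification,3
12A,p_mineralization,3
12A,iaa,1
12A,nitrification,0
25A,p_mineralization,3
25A,iaa,0
25A,nitrification,0
145A,p_mineralization,0
145A,iaa,3
145A,nitrification,0
50M,p_mineralization,2
50M,iaa,1
50M,nitrification,1
60M,p_mineralization,2
60M,iaa,1
60M,nitrification,1
20P,p_mineralization,0
20P,iaa,1
20P,nitrification,2
23P,p_mineralization,3
23P,iaa,3
23P,nitrification,0
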