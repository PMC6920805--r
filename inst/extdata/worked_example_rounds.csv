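isolate_id,round,group,parameter
36M,first,mesophilic,p_mineralization
40M,first,mesophilic,p_mineralization
97M,first,mesophilic,p_mineralization
54M,first,mesophilic,nitrification
58M,first,mesophilic,nitrification
114M,first,mesophilic,iaa
3B,first,spore_forming,p_mineralization
19B,first,spore_forming,nitrification
45B,first,spore_forming,iaa
89B,first,spore_forming,iaa
6P,first,pseudomonads,nitrification
10A,first,actinobacteria,nitrification
12A,first,actinobacteria,p_mineralization
25A,first,actinobacteria,p_mineralization
145A,first,actinobacteria,iaa
50M,second,mesophilic,NA
60M,second,mesophilic,NA
20P,second,pseudomonads,NA
23P,second,pseudomonads,NA
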