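isolate_id,group,viability_ok
36M,mesophilic,TRUE
40M,mesophilic,TRUE
50M,mesophilic,TRUE
54M,mesophilic,TRUE
58M,mesophilic,TRUE
60M,mesophilic,TRUE
97M,mesophilic,TRUE
114M,mesophilic,FALSE
3B,spore_forming,TRUE
19B,spore_forming,TRUE
45B,spore_forming,FALSE
89B,spore_forming,FALSE
6P,pseudomonads,TRUE
20P,pseudomonads,TRUE
23P,pseudomonads,TRUE
10A,actinobacteria,TRUE
12A,actinobacteria,TRUE
25A,actinobacteria,TRUE
145A,actinobacteria,TRUE
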