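group,parameter,q1,median,q3
mesophilic,p_mineralization,1.12,1.81,2.61
mesophilic,iaa,5.23,18.86,38.91
mesophilic,nitrification,1.48,13.13,17.51
spore_forming,p_mineralization,0.94,1.49,1.79
spore_forming,iaa,3.75,5.33,9.09
spore_forming,nitrification,0.78,1.62,1.97
pseudomonads,p_mineralization,0,0.91,0
pseudomonads,iaa,1.38,2.27,3.65
pseudomonads,nitrification,8.20,15.83,17.32
actinobacteria,p_mineralization,0.19,0.49,1.61
actinobacteria,iaa,4.25,7.21,26.38
actinobacteria,nitrification,0.91,2.44,8.16
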