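compound_id,formula,adduct,polarity,mean_ri,mean_rt_min
tryptophan,C11H12N2O2,[M+H]+,pos,475,5.29
riboflavin,C17H20N4O6,[M+H]+,pos,595,12.31
N-acetylphenylalanine,C11H13NO3,[M+H]+,pos,643,13.83
4-hydroxybenzoic acid,C7H6O3,[M+H]+,pos,521,6.85
3-hydroxybenzoic acid,C7H6O3,[M+H]+,pos,564,9.54
salicylic acid,C7H6O3,[M+H]+,pos,564,9.54
4-hydroxybenzoic acid,C7H6O3,[M-H]-,neg,521,6.85
3-hydroxybenzoic acid,C7H6O3,[M-H]-,neg,564,9.54
salicylic acid,C7H6O3,[M-H]-,neg,564,9.54
riboflavin,C17H20N4O6,[M-H]-,neg,595,12.31
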