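compound_id,formula,adduct,polarity,mean_ri,mean_rt_min
tryptophan,C11H12N2O2,[M+H]+,pos,474,2.71
riboflavin,C17H20N4O6,[M+H]+,pos,582,4.66
N-acetylphenylalanine,C11H13NO3,[M+H]+,pos,633,5.38
4-hydroxybenzoic acid,C7H6O3,[M+H]+,pos,511,3.40
3-hydroxybenzoic acid,C7H6O3,[M+H]+,pos,561,4.30
salicylic acid,C7H6O3,[M+H]+,pos,561,4.30
4-hydroxybenzoic acid,C7H6O3,[M-H]-,neg,511,3.40
3-hydroxybenzoic acid,C7H6O3,[M-H]-,neg,561,4.30
salicylic acid,C7H6O3,[M-H]-,neg,561,4.30
riboflavin,C17H20N4O6,[M-H]-,neg,582,4.65
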