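worked example genotypes
loc1
loc2
Pop
ind_1 , 010012 020020
ind_2 , 010010 020022
Pop
ind_3 , 014016 024024
ind_4 , 014014 024026
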