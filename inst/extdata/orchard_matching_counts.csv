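condition,cht_pairs,cht_correct,cluster_pairs,cluster_correct
SFP,392,310,112,103
SFN,88,71,25,24
SBP,360,293,103,98
SBN,135,112,38,37
CP,381,312,109,101
CN,157,113,45,42
Total,1513,1211,432,405
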