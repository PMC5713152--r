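condition,n_clusters,tp,fp,fn
SFP,112,102,12,10
SFN,25,23,9,2
SBP,103,97,9,6
SBN,38,35,5,3
CP,109,102,11,7
CN,45,42,3,3
Total,432,401,49,31
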