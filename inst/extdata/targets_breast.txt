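# Literature-curated breast-cancer target pathways (KEGG ids)
hsa04014
hsa04151
hsa04010
hsa04150
hsa04310
hsa04115
hsa01521
hsa04012
hsa04510
hsa04350
hsa04110
hsa05200
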