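probe_id,chrom,on_sex_chromosome,unique_hg19_alignment,contains_snp,on_epic
cg00000001,1,FALSE,TRUE,FALSE,TRUE
cg00000002,X,TRUE,TRUE,FALSE,TRUE
cg00000003,2,FALSE,FALSE,FALSE,TRUE
cg00000004,3,FALSE,TRUE,TRUE,TRUE
cg00000005,4,FALSE,TRUE,FALSE,FALSE
cg00000006,5,FALSE,TRUE,FALSE,TRUE
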