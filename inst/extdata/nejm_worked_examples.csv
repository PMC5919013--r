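# two published two-arm null results used as worked examples
# rows are treatment arms, columns are (event, no event)
study_id,row_index,col_index,count,row_label,col_label
jolly2015,0,0,347,PCI plus thrombectomy,death
jolly2015,0,1,4686,PCI plus thrombectomy,alive
jolly2015,1,0,351,PCI alone,death
jolly2015,1,1,4679,PCI alone,alive
carrier2015,0,0,5,screening plus CT,missed cancer
carrier2015,0,1,14,screening plus CT,detected
carrier2015,1,0,4,screening only,missed cancer
carrier2015,1,1,10,screening only,detected
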