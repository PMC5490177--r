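species,n_samples,n_success_species,pct_species,n_success_species_sex,pct_species_sex
Dichaetophora acutissima,3,3,100,NA,NA
Drosophila annulipes,14,14,100,7,50
Drosophila bizonata,18,16,89,10,56
Drosophila busckii,32,31,97,19,59
Drosophila curviceps,10,10,100,5,50
Drosophila hydei,17,15,88,6,35
Drosophila immigrans,38,33,87,29,76
Drosophila lutescens,20,20,100,NA,NA
Drosophila rufa,38,35,92,20,53
Drosophila sternopleuralis,38,36,95,17,45
Hirtodrosophila sexvittata,38,32,84,22,58
Liodrosophila aerea,38,38,100,25,66
Scaptodrosophila coracina,17,16,94,11,65
Scaptomyza graminum,24,22,92,8,33
Microdrosophila sp.,25,25,100,NA,NA
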