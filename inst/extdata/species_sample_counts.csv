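species,female,male
Dichaetophora acutissima,20,25
Drosophila annulipes,31,27
Drosophila bizonata,31,31
Drosophila busckii,35,41
Drosophila curviceps,20,26
Drosophila hydei,11,20
Drosophila immigrans,41,41
Drosophila lutescens,14,42
Drosophila rufa,41,41
Drosophila sternopleuralis,42,42
Drosophila suzukii,22,19
Hirtodrosophila sexvittata,41,41
Liodrosophila aerea,41,41
Microdrosophila sp.,15,10
Scaptodrosophila coracina,5,34
Scaptomyza graminum,36,32
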