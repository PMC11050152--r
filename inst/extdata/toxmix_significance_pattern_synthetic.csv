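"gene","treatment","significant"
"ALDH3A1","Retene",TRUE
"ALDH3A1","Benzo[a]fluorene",TRUE
"ALDH3A1","Benzo[b]fluorene",TRUE
"ALDH3A1","Benzo[c]fluorene",FALSE
"ALDH3A1","Triphenylene",TRUE
"ALDH3A1","Benzo[e]pyrene",FALSE
"ALDH3A1","Benzo[ghi]perylene",FALSE
"CYP1A1","Retene",TRUE
"CYP1A1","Benzo[a]fluorene",TRUE
"CYP1A1","Benzo[b]fluorene",TRUE
"CYP1A1","Benzo[c]fluorene",TRUE
"CYP1A1","Triphenylene",TRUE
"CYP1A1","Benzo[e]pyrene",TRUE
"CYP1A1","Benzo[ghi]perylene",TRUE
"CYP1B1","Retene",TRUE
"CYP1B1","Benzo[a]fluorene",TRUE
"CYP1B1","Benzo[b]fluorene",TRUE
"CYP1B1","Benzo[c]fluorene",FALSE
"CYP1B1","Triphenylene",FALSE
"CYP1B1","Benzo[e]pyrene",TRUE
"CYP1B1","Benzo[ghi]perylene",TRUE
"GSTA","Retene",TRUE
"GSTA","Benzo[a]fluorene",TRUE
"GSTA","Benzo[b]fluorene",TRUE
"GSTA","Benzo[c]fluorene",TRUE
"GSTA","Triphenylene",TRUE
"GSTA","Benzo[e]pyrene",FALSE
"GSTA","Benzo[ghi]perylene",FALSE
"HMOX1","Retene",TRUE
"HMOX1","Benzo[a]fluorene",TRUE
"HMOX1","Benzo[b]fluorene",TRUE
"HMOX1","Benzo[c]fluorene",FALSE
"HMOX1","Triphenylene",FALSE
"HMOX1","Benzo[e]pyrene",TRUE
"HMOX1","Benzo[ghi]perylene",TRUE
"NQO1","Retene",TRUE
"NQO1","Benzo[a]fluorene",FALSE
"NQO1","Benzo[b]fluorene",TRUE
"NQO1","Benzo[c]fluorene",TRUE
"NQO1","Triphenylene",FALSE
"NQO1","Benzo[e]pyrene",FALSE
"NQO1","Benzo[ghi]perylene",TRUE
"GJA1","Retene",FALSE
"GJA1","Benzo[a]fluorene",FALSE
"GJA1","Benzo[b]fluorene",FALSE
"GJA1","Benzo[c]fluorene",FALSE
"GJA1","Triphenylene",FALSE
"GJA1","Benzo[e]pyrene",FALSE
"GJA1","Benzo[ghi]perylene",FALSE
"TJP2","Retene",FALSE
"TJP2","Benzo[a]fluorene",TRUE
"TJP2","Benzo[b]fluorene",FALSE
"TJP2","Benzo[c]fluorene",FALSE
"TJP2","Triphenylene",FALSE
"TJP2","Benzo[e]pyrene",FALSE
"TJP2","Benzo[ghi]perylene",TRUE
"DDB2","Retene",FALSE
"DDB2","Benzo[a]fluorene",FALSE
"DDB2","Benzo[b]fluorene",FALSE
"DDB2","Benzo[c]fluorene",FALSE
"DDB2","Triphenylene",FALSE
"DDB2","Benzo[e]pyrene",FALSE
"DDB2","Benzo[ghi]perylene",FALSE
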