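# Published global pairwise Weir-Cockerham FST between eight northeast
# Pacific marine threespine stickleback sampling sites (all pairs
# significantly > 0 in the original permutation tests); fixture values.
site,CA01,CA02,CA03,OR01,OR02,WA01,BC01,AK01
CA01,0,0.096,0.110,0.121,0.181,0.146,0.157,0.096
CA02,0.096,0,0.059,0.063,0.134,0.082,0.095,0.052
CA03,0.110,0.059,0,0.044,0.100,0.079,0.094,0.058
OR01,0.121,0.063,0.044,0,0.082,0.045,0.056,0.032
OR02,0.181,0.134,0.100,0.082,0,0.142,0.159,0.092
WA01,0.146,0.082,0.079,0.045,0.142,0,0.027,0.020
BC01,0.157,0.095,0.094,0.056,0.159,0.027,0,0.022
AK01,0.096,0.052,0.058,0.032,0.092,0.020,0.022,0
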