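individual,locus,allele1,allele2
mother,MS01,200,204
mother,MS02,210,214
mother,MS03,220,220
mother,MS04,230,234
mother,MS05,240,244
mother,MS06,250,250
mother,MS07,260,260
mother,MS08,270,274
male_A,MS01,180,182
male_A,MS02,190,194
male_A,MS03,198,198
male_A,MS04,206,210
male_A,MS05,214,218
male_A,MS06,222,222
male_A,MS07,230,234
male_A,MS08,238,242
male_B,MS01,184,186
male_B,MS02,188,192
male_B,MS03,196,200
male_B,MS04,204,208
male_B,MS05,212,216
male_B,MS06,220,224
male_B,MS07,228,232
male_B,MS08,270,270
hatchling_1,MS01,200,200
hatchling_1,MS02,210,210
hatchling_1,MS03,220,220
hatchling_1,MS04,230,230
hatchling_1,MS05,240,240
hatchling_1,MS06,250,250
hatchling_1,MS07,260,260
hatchling_1,MS08,270,270
hatchling_2,MS01,204,204
hatchling_2,MS02,214,214
hatchling_2,MS03,220,220
hatchling_2,MS04,234,234
hatchling_2,MS05,240,240
hatchling_2,MS06,250,250
hatchling_2,MS07,260,260
hatchling_2,MS08,270,270
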