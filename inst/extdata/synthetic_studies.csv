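"study_id","n","r_pa_mpa","r_pa_sc","r_sc_mpa","educational_stage","region","scale_pair"
"sim_001",518,-0.209326728645556,0.314460635105216,-0.475242361087526,"secondary","mainland_china","PARS+MPATS"
"sim_002",209,-0.282546395054632,NA,NA,"college","mainland_china","PARS+MPATS"
"sim_003",716,-0.0937086241996773,NA,NA,"secondary","mainland_china","IPAQ+SAS"
"sim_004",141,-0.338079289094023,NA,NA,"college","other","IPAQ+SAS"
"sim_005",224,-0.188121132364658,0.175575444490307,-0.487683744620749,"college","mainland_china","PARS+MPATS"
"sim_006",380,-0.0902188091751276,0.210310312212043,-0.465871379007913,"secondary","other","other"
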