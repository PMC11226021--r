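"query","sample","uid","mode","area","rt","match_factor"
"octanal","sample_01","sample_01#3","name","37349","6.25","98.5863021393307"
"octanal","sample_02","sample_02#3","name","206056","6.25","80.7397933313623"
"octanal","sample_03","sample_03#3","name","84059","6.25","83.9628291819245"
"limonene","sample_01","sample_01#6","name","109192","8.5","80.0750184371136"
"limonene","sample_02","sample_02#6","name","274299","8.5","84.1113228860777"
"limonene","sample_03","sample_03#6","name","17178","8.5","91.5698115983978"
"ethyl hexanoate","sample_01","sample_01#1","name","675479","4.75","92.1931648589671"
"ethyl hexanoate","sample_02","sample_02#1","name","297287","4.75","80.7111896243878"
"ethyl hexanoate","sample_03","sample_03#1","name","740192","4.75","91.0504760476761"
"methyl salicylate","sample_01","sample_01#2","name","748429","5.5","88.6970937487204"
"methyl salicylate","sample_02","sample_02#2","name","18592","5.5","98.4483655968215"
"methyl salicylate","sample_03","sample_03#2","name","32423","5.5","84.4403645736165"
"linalool","sample_01","sample_01#5","name","192084","7.75","88.4924229339231"
"linalool","sample_02","sample_02#5","name","82316","7.75","85.1544456793927"
"linalool","sample_03","sample_03#5","name","904592","7.75","97.9066581476945"
"undecane","sample_01","sample_01#4","name","458031","7","98.7889428494964"
"undecane","sample_02","sample_02#4","name","257116","7","92.8365382158663"
"undecane","sample_03","sample_03#4","name","758628","7","94.1355182800908"
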