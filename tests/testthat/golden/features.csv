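"Compound.Name","File.Name","Base.Peak.MZ","Match.Factor","Component.RT","Component.Area"
"ethyl hexanoate","sample_01","43","92.1931648589671","4.75","675479"
"methyl salicylate","sample_01","46","88.6970937487204","5.5","748429"
"octanal","sample_01","49","98.5863021393307","6.25","37349"
"undecane","sample_01","52","98.7889428494964","7","458031"
"linalool","sample_01","55","88.4924229339231","7.75","192084"
"limonene","sample_01","58","80.0750184371136","8.5","109192"
"Cyclotetrasiloxane, octamethyl-","sample_01","281","85.1026780563407","11.25","26021"
"ethyl hexanoate","sample_02","43","80.7111896243878","4.75","297287"
"methyl salicylate","sample_02","46","98.4483655968215","5.5","18592"
"octanal","sample_02","49","80.7397933313623","6.25","206056"
"undecane","sample_02","52","92.8365382158663","7","257116"
"linalool","sample_02","55","85.1544456793927","7.75","82316"
"limonene","sample_02","58","84.1113228860777","8.5","274299"
"Cyclotetrasiloxane, octamethyl-","sample_02","281","87.7637447919697","11.25","274607"
"ethyl hexanoate","sample_03","43","91.0504760476761","4.75","740192"
"methyl salicylate","sample_03","46","84.4403645736165","5.5","32423"
"octanal","sample_03","49","83.9628291819245","6.25","84059"
"undecane","sample_03","52","94.1355182800908","7","758628"
"linalool","sample_03","55","97.9066581476945","7.75","904592"
"limonene","sample_03","58","91.5698115983978","8.5","17178"
"Cyclotetrasiloxane, octamethyl-","sample_03","281","95.5213158777915","11.25","80438"
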