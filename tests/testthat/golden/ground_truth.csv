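"chemical","sample","true_area"
"ethyl hexanoate","sample_01","675479"
"methyl salicylate","sample_01","748429"
"octanal","sample_01","37349"
"undecane","sample_01","458031"
"linalool","sample_01","192084"
"limonene","sample_01","109192"
"ethyl hexanoate","sample_02","297287"
"methyl salicylate","sample_02","18592"
"octanal","sample_02","206056"
"undecane","sample_02","257116"
"linalool","sample_02","82316"
"limonene","sample_02","274299"
"ethyl hexanoate","sample_03","740192"
"methyl salicylate","sample_03","32423"
"octanal","sample_03","84059"
"undecane","sample_03","758628"
"linalool","sample_03","904592"
"limonene","sample_03","17178"
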