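"chemical","optimal_rt","exact_mass","best_match_factor","sample_01","sample_02","sample_03"
"octanal","6.25","128.1201151325","98.5863021393307","37349","206056","84059"
"limonene","8.5","136.1252005104","91.5698115983978","109192","274299","17178"
"ethyl hexanoate","4.75","144.1150297546","92.1931648589671","675479","297287","740192"
"methyl salicylate","5.5","152.0473441215","98.4483655968215","748429","18592","32423"
"linalool","7.75","154.1357651963","97.9066581476945","192084","82316","904592"
"undecane","7","156.1878007656","98.7889428494964","458031","257116","758628"
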