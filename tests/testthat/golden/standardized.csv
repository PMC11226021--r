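"chemical","optimal_rt","exact_mass","best_match_factor","sample_01","sample_02","sample_03","extrapolated_in"
"octanal","6.25","128.1201151325","98.5863021393307","0.81542515681253","8.01412591981829","1.10803977707124",""
"limonene","8.5","136.1252005104","91.5698115983978","2.383943444876","10.668297577747","0.226435090716399",""
"ethyl hexanoate","4.75","144.1150297546","92.1931648589671","14.7474515917045","11.5623687362902","9.75698234180653",""
"methyl salicylate","5.5","152.0473441215","98.4483655968215","16.3401385495742","0.723097745764558","0.427389972423902",""
"linalool","7.75","154.1357651963","97.9066581476945","4.19368994675033","3.2015121579365","11.9240523682226",""
"undecane","7","156.1878007656","98.7889428494964","10","10","10",""
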