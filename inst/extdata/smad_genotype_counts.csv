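locus,genotype,count
g.51537A>G,AA,256
g.51537A>G,AG,150
g.51537A>G,GG,27
g.319C>T,CC,409
g.319C>T,CT,24
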