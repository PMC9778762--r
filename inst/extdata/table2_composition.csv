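part,length,start,end,at_pct,gc_pct
I,327,1,327,49.8,50.2
II,326,328,653,57.1,42.9
III,327,654,980,72.2,27.8
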