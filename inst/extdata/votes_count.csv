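"participant","count"
"p01",10
"p02",10
"p03",10
"p04",10
"p05",10
"p06",10
"p07",10
"p08",10
"p09",10
"p10",10
"p11",10
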