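site	pos
triad_asn	41
triad_his	60
triad_cys	100
lad1_1	120
lad1_2	121
gk	121
lad2_1	130
mla_start	140
mla_end	159
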