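site	role	pos
longrange_1	long_range	10
outer_1	outer_active,regulatory	20
outer_2	outer_active,regulatory	25
regulatory_3	regulatory	30
regulatory_4	regulatory	40
pdi_1	pdi_interacting	55
pdi_2	pdi_interacting	65
noncatalytic_268	noncatalytic	80
longrange_2	long_range	92
inner_1	inner_active	100
inner_2	inner_active	103
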