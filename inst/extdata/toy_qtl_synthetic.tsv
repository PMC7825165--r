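chr1	20000	120000	Milk_yield
chr1	150000	260000	Carcass_weight
chr1	300000	340000	Horn_type
chr2	10000	90000	Wool_fineness
chr2	120000	180000	Body_weight
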