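name	r1c1	r1c2	r2c1	r2c2
mmr_loss_by_carrier_status	69	5	17	6
retained_expression_by_location	2	59	9	27
fdr_location_by_expression	14	1	3	5
carrier_location_by_expression	45	1	24	4
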