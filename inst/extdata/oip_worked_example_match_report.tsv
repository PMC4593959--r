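ion	theo_mz	theo_rel	exp_mz	exp_abund	exp_rel	ipmd	ipad	is_oip	verdict
y10-1+	1141.607714	63.64	1141.613770	128926.921875	63.64	5	0	FALSE	non-matching
y10-1+	1142.610419	23.01	1142.617676	480992.312500	237.41	6	214	TRUE	non-matching
y20-2+	1142.611961	100.00	1142.617676	480992.312500	115.48	5	15	TRUE	matching
y20-2+	1143.113357	67.65	1143.120117	281777.062500	67.65	6	0	FALSE	matching
y72-7+	1142.607764	55.06	1142.617676	480992.312500	397.99	9	343	TRUE	non-matching
y72-7+	1142.894250	100.00	1142.910522	120854.796875	100.00	14	0	FALSE	non-matching
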