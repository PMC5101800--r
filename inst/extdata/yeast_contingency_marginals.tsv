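organism	rate	dataset	metric	total_positive	observed_optimal	n_optimal
S. cerevisiae	half_life	Cramer (1)	cTE	25	23	24
S. cerevisiae	half_life	Cramer (2)	cTE	26	18	24
S. cerevisiae	half_life	Gresham	cTE	22	16	24
S. pombe	half_life	Mata (5)	cTE	27	24	28
S. pombe	half_life	Gagneur	cTE	26	22	28
S. cerevisiae	half_life	Cramer (1)	nTE	25	21	30
S. cerevisiae	half_life	Cramer (2)	nTE	26	19	30
S. cerevisiae	half_life	Gresham	nTE	22	17	30
S. pombe	half_life	Mata (5)	nTE	27	22	35
S. pombe	half_life	Gagneur	nTE	26	21	35
S. cerevisiae	synthesis	Cramer (1)	cTE	23	23	24
S. cerevisiae	synthesis	Cramer (2)	cTE	22	17	24
S. cerevisiae	synthesis	Gresham	cTE	23	22	24
S. pombe	synthesis	Bahler	cTE	27	25	28
S. pombe	synthesis	Mata (5)	cTE	21	18	28
S. pombe	synthesis	Gagneur	cTE	26	24	28
S. cerevisiae	synthesis	Cramer (1)	nTE	23	20	30
S. cerevisiae	synthesis	Cramer (2)	nTE	22	16	30
S. cerevisiae	synthesis	Gresham	nTE	23	19	30
S. pombe	synthesis	Bahler	nTE	27	23	35
S. pombe	synthesis	Mata (5)	nTE	21	18	35
S. pombe	synthesis	Gagneur	nTE	26	22	35
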