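classification	in_group	deletion	n
t_lineage	yes	pos	0
t_lineage	yes	neg	109
t_lineage	no	pos	65
t_lineage	no	neg	657
hyperdiploid	yes	pos	5
hyperdiploid	yes	neg	155
hyperdiploid	no	pos	55
hyperdiploid	no	neg	422
etv6_runx1	yes	pos	27
etv6_runx1	yes	neg	115
etv6_runx1	no	pos	22
etv6_runx1	no	neg	349
bcr_abl1	yes	pos	6
bcr_abl1	yes	neg	17
bcr_abl1	no	pos	52
bcr_abl1	no	neg	573
mll	yes	pos	0
mll	yes	neg	17
mll	no	pos	55
mll	no	neg	577
other	yes	pos	13
other	yes	neg	167
other	no	pos	38
other	no	neg	304
unknown	yes	pos	14
unknown	yes	neg	186
unknown	no	pos	51
unknown	no	neg	471
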