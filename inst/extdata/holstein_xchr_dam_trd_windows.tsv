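# Published mating-genotype counts for 20-SNP haplotype windows with
# significant dam-TRD on the heterosomal X chromosome of North American
# Holstein cattle (biallelic haplotype coding: focal haplotype = pseudo-allele
# A versus all others pooled as B; UMD3.1 bp coordinates "start:end").
# Offspring-category columns follow the heterosomal layout described in
# holstein_xchr_dam_trd_snps.tsv. printed_alpha_d / printed_log10_bf: the
# published posterior mean and log10 Bayes factor for the row.
window	n_het_dams	axab_aa_a	axab_ab	axab_b	bxab_a	bxab_ab	bxab_bb_b	printed_alpha_d	printed_log10_bf
134602363:135936247	10	0	0	0	0	0	72	-0.49	19.80
134841753:136063445	11	0	0	0	0	0	72	-0.49	19.80
134624675:135970186	10	0	0	0	0	0	71	-0.49	19.51
119781376:121600055	11	0	0	0	1	4	91	-0.44	19.13
123894981:125905926	101	0	0	0	46	72	310	-0.22	18.12
53138058:58932871	18	0	0	0	3	10	103	-0.38	16.11
56821723:59606508	12	0	0	0	0	1	56	-0.47	13.65
56846129:59878165	12	0	0	0	0	1	56	-0.47	13.65
129911571:132268728	15	0	0	0	0	3	62	-0.44	13.11
130070306:132334180	15	0	0	0	0	3	62	-0.44	13.11
130112536:132620448	15	0	0	0	0	3	62	-0.44	13.11
55893493:59564066	44	0	0	0	31	40	199	-0.24	12.55
129070088:131766182	12	0	0	0	1	1	53	-0.45	11.64
129145800:131806987	12	0	0	0	1	1	53	-0.45	11.64
129193110:131960783	12	0	0	0	1	1	53	-0.45	11.64
129718409:132109716	12	0	0	0	1	1	53	-0.45	11.64
129887133:132211189	12	0	0	0	1	1	53	-0.45	11.64
23761259:26607222	30	0	0	0	5	25	118	-0.29	11.07
56962509:60125574	13	0	0	0	2	4	62	-0.40	10.59
100533235:105003475	14	0	0	0	5	3	67	-0.38	10.47
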