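# Published per-SNP mating-genotype counts for significant dam-TRD on the
# heterosomal X chromosome of North American Holstein cattle (sire-dam-offspring
# trios; UMD3.1 coordinates). Offspring columns follow the heterosomal layout:
# sire hemizygous A x dam AB matings yield offspring AA/A (dam-A), AB (dam-B,
# daughters) and B (dam-B, sons); sire hemizygous B x dam AB matings yield A
# (dam-A, sons), AB (dam-A, daughters) and BB/B (dam-B). stratum: pooled (-),
# M (male offspring) or F (female offspring). printed_alpha_d/printed_log10_bf:
# the published posterior mean and log10 Bayes factor for that row.
pos_bp	stratum	n_het_dams	axab_aa_a	axab_ab	axab_b	bxab_a	bxab_ab	bxab_bb_b	printed_alpha_d	printed_log10_bf
4134094	pooled	391	111	46	88	209	150	623	-0.12	13.3
40239653	pooled	42334	37552	23430	11719	7816	15685	22229	0.02	20.6
85463982	pooled	13963	294	241	98	3401	9983	14552	-0.02	9.2
2230488	M	640	854	0	668	58	0	39	0.06	4.14
2230488	F	477	632	628	0	0	20	18	0.00	NA
67099097	M	785	1192	0	1146	53	0	41	0.01	NA
67099097	F	504	936	586	0	0	28	37	0.11	14.5
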