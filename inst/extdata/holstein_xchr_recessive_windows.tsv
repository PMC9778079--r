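# Published female-offspring mating-genotype counts for haplotype windows with
# a recessive TRD pattern on the heterosomal X chromosome of North American
# Holstein cattle (window "start:end" in UMD3.1 bp; n_snps = window size).
# Categories: hemizygous-A sire x heterozygous dam daughters (AA, AB) and
# hemizygous-B sire x heterozygous dam daughters (AB, BB), with the focal
# haplotype as allele A. printed_alpha_g / printed_delta_g: the published
# additive and dominance genotypic-TRD posterior means.
window	n_snps	n_het_dams	aaxab_aa	aaxab_ab	bbxab_ab	bbxab_bb	printed_alpha_g	printed_delta_g
307557:854184	10	247	2	8	300	281	-0.34	0.21
14897141:16123681	10	452	1	8	559	579	-0.47	0.21
23895384:27387980	20	541	1	7	674	634	-0.40	0.24
30116443:30459667	4	574	0	6	683	689	-0.51	0.25
48750092:52808614	20	592	0	5	647	669	-0.50	0.23
59564066:61635072	20	525	0	8	550	549	-0.56	0.28
109041641:110425524	20	438	1	8	513	539	-0.48	0.21
127431846:129887133	20	406	2	9	573	551	-0.37	0.21
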