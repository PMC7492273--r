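# Packaged 50-species GMHI signature (7 health-prevalent H+, 43 health-scarce H-)
# selected at prevalence fold-change threshold 1.4 and difference threshold 10%.
# p_h / p_n are the discovery prevalences in the healthy / nonhealthy groups,
# in percent as printed; diff_printed and fold_printed are the published
# difference and larger-over-smaller fold-change cells (1-decimal rounding).
species	set	p_h	p_n	diff_printed	fold_printed
Alistipes senegalensis	H+	58.5	39.9	18.5	1.5
Bacteroidales bacterium ph8	H+	73.1	51.4	21.8	1.4
Bifidobacterium adolescentis	H+	68.2	46.4	21.9	1.5
Bifidobacterium angulatum	H+	11.9	1.5	10.4	7.8
Bifidobacterium catenulatum	H+	30.8	13.5	17.3	2.3
Lachnospiraceae bacterium 8_1_57FAA	H+	44.8	26.9	17.9	1.7
Sutterella wadsworthensis	H+	48.1	26.2	21.8	1.8
Anaerotruncus colihominis	H-	23.1	37.4	-14.3	1.6
Atopobium parvulum	H-	2.3	12.7	-10.4	5.6
Bifidobacterium dentium	H-	6.6	16.7	-10.1	2.5
Blautia producta	H-	5.0	15.6	-10.6	3.1
Candidatus Saccharibacteria TM7c	H-	1.9	13.2	-11.3	6.8
Clostridiales bacterium 1_7_47FAA	H-	16.2	40.0	-23.8	2.5
Clostridium asparagiforme	H-	20.8	44.1	-23.3	2.1
Clostridium bolteae	H-	34.5	69.7	-35.3	2.0
Clostridium citroniae	H-	23.9	50.4	-26.5	2.1
Clostridium clostridioforme	H-	9.8	26.1	-16.4	2.7
Clostridium hathewayi	H-	26.9	56.1	-29.2	2.1
Clostridium nexile	H-	14.3	31.7	-17.4	2.2
Clostridium ramosum	H-	10.8	31.9	-21.1	3.0
Clostridium symbiosum	H-	20.9	47.5	-26.6	2.3
Eggerthella lenta	H-	18.9	37.4	-18.5	2.0
Erysipelotrichaceae bacterium 2_2_44A	H-	18.5	33.4	-14.9	1.8
Flavonifractor plautii	H-	34.9	56.5	-21.6	1.6
Fusobacterium nucleatum	H-	2.2	12.3	-10.1	5.7
Gemella morbillorum	H-	1.4	11.7	-10.3	8.1
Gemella sanguinis	H-	5.9	21.0	-15.2	3.6
Granulicatella adiacens	H-	3.4	21.4	-18.0	6.3
Holdemania filiformis	H-	36.9	57.3	-20.4	1.6
Klebsiella pneumoniae	H-	17.4	34.3	-16.9	2.0
Lachnospiraceae bacterium 1_4_56FAA	H-	18.1	38.0	-19.9	2.1
Lachnospiraceae bacterium 2_1_58FAA	H-	33.6	47.1	-13.5	1.4
Lachnospiraceae bacterium 3_1_57FAA_CT1	H-	18.3	35.9	-17.7	2.0
Lachnospiraceae bacterium 5_1_57FAA	H-	6.9	18.9	-12.0	2.7
Lachnospiraceae bacterium 9_1_43BFAA	H-	5.5	16.2	-10.7	3.0
Lactobacillus salivarius	H-	3.8	14.3	-10.5	3.7
Peptostreptococcus stomatis	H-	1.9	13.7	-11.8	7.4
Ruminococcaceae bacterium D16	H-	16.4	31.3	-15.0	1.9
Ruminococcus gnavus	H-	41.8	68.0	-26.2	1.6
Solobacterium moorei	H-	7.4	32.2	-24.8	4.4
Streptococcus anginosus	H-	10.8	30.2	-19.4	2.8
Streptococcus australis	H-	26.9	42.0	-15.0	1.6
Streptococcus gordonii	H-	6.7	22.6	-15.9	3.4
Streptococcus infantis	H-	12.5	28.2	-15.8	2.3
Streptococcus mitis/oralis/pneumoniae	H-	12.3	32.9	-20.6	2.7
Streptococcus sanguinis	H-	14.4	31.9	-17.5	2.2
Streptococcus vestibularis	H-	16.2	30.7	-14.5	1.9
Subdoligranulum sp. 4_3_54A2FAA	H-	5.9	16.7	-10.8	2.8
Subdoligranulum variabile	H-	6.9	17.3	-10.4	2.5
Veillonella atypica	H-	22.5	34.5	-12.0	1.5
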