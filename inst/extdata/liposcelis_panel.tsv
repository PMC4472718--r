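target	name	role	sequence	length	gc	tm	dg	any	end3	dye	quencher	ex	em	channel	use
Liposcelis brunnea	BruCo5F	forward	GGGGTTTTAGGGTTTGTGGTA	21	47.2	60.0	0.8	2	2	NA	NA	NA	NA	NA	both
Liposcelis brunnea	BruCo5R	reverse	AATGTCGCCAACCATCTAAAG	21	42.9	59.1	0	4	2	NA	NA	NA	NA	NA	both
Liposcelis brunnea	BruCo6F	forward	TTTATGCGATAGGAGCGATTG	21	42.9	60.2	0.5	4	2	NA	NA	NA	NA	NA	single
Liposcelis brunnea	BruCo6R	reverse	CATCCAACCCGACAGTAAACA	21	47.7	60.7	1.0	3	0	NA	NA	NA	NA	NA	single
Liposcelis bostrychophila	BosCo7F	forward	CGATCCCTACCGGAGTTAAAG	21	52.4	60.0	0.7	4	1	NA	NA	NA	NA	NA	endpoint
Liposcelis bostrychophila	BosCo7R	reverse	TGGGCAACAACATAGTATCTATCG	24	41.7	60.3	0.7	6	4	NA	NA	NA	NA	NA	endpoint
Liposcelis bostrychophila	BosCo8F	forward	ATGCTCTCAATCGGAGCTCTAG	22	50.0	60.1	0.7	6	4	NA	NA	NA	NA	NA	qpcr
Liposcelis bostrychophila	BosCo8R	reverse	ACTTTAACTCCGGTAGGGATCG	22	50.0	60.7	0.9	4	2	NA	NA	NA	NA	NA	qpcr
Liposcelis bostrychophila	BosCo9F	forward	TGGGCTAATCTCTCACATCATCT	23	43.5	60.1	0.9	3	3	NA	NA	NA	NA	NA	single
Liposcelis decolor	DecCo10F	forward	CCGGCTTTTGGTATTATTTCAC	22	40.9	59.8	0.7	4	1	NA	NA	NA	NA	NA	single
Liposcelis decolor	DecCo10R	reverse	ATTATCCCCATTACCCCAAA	20	40.0	58.0	0.9	3	0	NA	NA	NA	NA	NA	single
Liposcelis decolor	DecCo11F	forward	CGAGCTTATTTTACTTCTGCGACT	24	41.7	60.4	0.9	4	1	NA	NA	NA	NA	NA	both
Liposcelis decolor	DecCo11R	reverse	TGATCCATACAACGTAGCTAGTCA	24	41.7	58.9	1.0	6	2	NA	NA	NA	NA	NA	both
Liposcelis obscura	ObsCo12F	forward	GGACAGGGTGGACGGTTTATC	21	57.1	62.8	1.0	3	1	NA	NA	NA	NA	NA	qpcr
Liposcelis obscura	ObsCo12R	reverse	CTGATTCCTGCTAAATGAAGAGAG	24	41.7	58.8	0.9	3	0	NA	NA	NA	NA	NA	qpcr
Liposcelis obscura	ObsCo13F	forward	AGCTATTGCTCACGGAGGATA	21	47.6	59.0	0	6	4	NA	NA	NA	NA	NA	endpoint
Liposcelis obscura	ObsCo13R	reverse	CCAATTGCGGACATAGCATAA	21	42.9	60.8	1.0	6	1	NA	NA	NA	NA	NA	endpoint
Liposcelis pearmani	PeaCo14F	forward	CTGACTTTTTCCCCCTTCACT	21	47.6	59.6	0.9	3	1	NA	NA	NA	NA	NA	qpcr
Liposcelis pearmani	PeaCo14R	reverse	GCCAGGGTGTGAGATTCTAAA	21	47.6	59.2	0.9	5	3	NA	NA	NA	NA	NA	both
Liposcelis pearmani	PeaCo15F	forward	TGGTGTGTGAGCAGGTATGGT	21	52.4	61.5	0.8	2	0	NA	NA	NA	NA	NA	endpoint
Liposcelis decolor	DecCo11P	probe	TGCTGTTCCTACAGGAATCAAGGTTTT	27	41	NA	1.0	8	0	6-FAM	BHQ2	495	520	green	both
Liposcelis brunnea	BruCo5P	probe	TGTTTACTGTCGGGTTGGATGTGGA	25	48	NA	0.9	3	0	HEX	ZEN-IABkFQ	535	554	yellow	both
Liposcelis obscura	ObsCo12P	probe	CCTCAGCTATTGCTCACGGAGGA	23	56	NA	0.9	6	4	6-ROXN	BHQ2	575	602	orange	qpcr
Liposcelis bostrychophila	BosCo8P	probe	GGGCATGGATGTGGATAGACGAGC	24	58	NA	1.0	4	2	Cy5	BHQ2	647	667	red	qpcr
Liposcelis pearmani	PeaCo14P	probe	AGGGAGTCGGAACCGGGTGAA	21	62	NA	0.8	5	0	Quasar705	BHQ3	690	705	crimson	qpcr
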