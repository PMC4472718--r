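assay	target	forward	reverse	probe	use	genomic_size	apc_size
ObsCo13	Liposcelis obscura	ObsCo13F	ObsCo13R	NA	endpoint	438	322
PeaCo15	Liposcelis pearmani	PeaCo15F	PeaCo14R	NA	endpoint	351	241
BosCo7	Liposcelis bostrychophila	BosCo7F	BosCo7R	NA	endpoint	191	184
BruCo5	Liposcelis brunnea	BruCo5F	BruCo5R	BruCo5P	both	140	140
DecCo11	Liposcelis decolor	DecCo11F	DecCo11R	DecCo11P	both	87	99
ObsCo12	Liposcelis obscura	ObsCo12F	ObsCo12R	ObsCo12P	qpcr	100	72
PeaCo14	Liposcelis pearmani	PeaCo14F	PeaCo14R	PeaCo14P	qpcr	115	67
BosCo8	Liposcelis bostrychophila	BosCo8F	BosCo8R	BosCo8P	qpcr	131	96
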