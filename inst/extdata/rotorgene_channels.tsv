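name	source_nm	detect_nm
green	470	510
yellow	530	555
orange	585	610
red	625	660
crimson	680	712
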