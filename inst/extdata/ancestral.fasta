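>ancestral_core assembled 75-nt core (AS5+DMH+DREM+ACMH+VLOOP+TMH+AS3)
GCGGCCGTAGTCTAGCCTGGACTAGACCGCCGGGCTTGTAACCCGGTGGTCCCGGGTTCAAATCCCGGCGGCCGC
>acc5 ancestral 5' acceptor stem (1-7)
GCGGCCG
>acc3 ancestral 3' acceptor stem (69-75)
CGGCCGC
>d_relic ancestral D-loop acceptor-stem relic (25-29)
GACCG
>v_relic ancestral V-loop acceptor-stem relic (47-51)
TGGTC
>d_microhelix ancestral D-loop 17-nt microhelix (GCC anticodon)
TAGTCTAGCCTGGACTA
>ac_microhelix anticodon-loop 17-nt microhelix (TGT placeholder anticodon)
CCGGGCTTGTAACCCGG
>t_microhelix ancestral T-loop 17-nt microhelix (CAA anticodon)
CCGGGTTCAAATCCCGG
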