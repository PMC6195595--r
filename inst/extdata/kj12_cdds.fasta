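>Kj12B-CDD role=CDD offset=1545
LLKEKRKHFQAEQNSSQEYLRGEI
>Kj12B-CDD_short role=CDD offset=1561
QEYLRGEI
>Kj12A-CDD_peptide role=CDD offset=1 non-native_N-terminal_tyrosine
YLVKEKRKHFQTEQEKTQKLLFGHI
>Kj12A-CDD_beta3 role=CDD offset=1168 register_fixture_(reported_chemistry)
LEGHI
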