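ndd,cdd,cdd_mutations,kd_um,kd_err_um,censored,provenance
Kj12C,Kj12B,,8,6,FALSE,ITC
Kj12A,Kj12B,,8,4,FALSE,ITC
Kj12B,Kj12B,,62,8,FALSE,ITC (buffer-subtracted; not saturated)
Kj12C,Kj12A,,100,NA,FALSE,ITC (approximate)
Kj12C,Kj12B_short,,15,3,FALSE,ITC
Kj12B,Kj12B,R1565E,13,1,FALSE,ITC (buffer-subtracted; not saturated)
Kj12C,Kj12A,"E1169R,H1171E",3.5,0.1,FALSE,ITC
Kj12A,Kj12A,,NA,NA,TRUE,too weak to quantify
Kj12B,Kj12A,,NA,NA,TRUE,too weak to quantify
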