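adduct	mass_delta	charge	polarity
[M+H]+	1.00727645216054	1	positive
[M+Na]+	22.9892207009905	1	positive
[M+K]+	38.9631581000905	1	positive
[M+NH4]+	18.0338255531705	1	positive
[M+2H]2+	2.01455290432108	2	positive
[M-H]-	-1.00727645216054	-1	negative
[M+Cl]-	34.9694012599095	-1	negative
[M+HCOO]-	44.9982028511795	-1	negative
[M-2H]2-	-2.01455290432108	-2	negative
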