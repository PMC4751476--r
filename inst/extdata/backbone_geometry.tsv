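parameter	value	units
b_N_CA	1.458	angstrom
b_CA_C	1.525	angstrom
b_C_N	1.329	angstrom
b_C_O	1.231	angstrom
b_CA_CB	1.521	angstrom
a_N_CA_C	111.2	degrees
a_CA_C_N	116.2	degrees
a_C_N_CA	121.7	degrees
a_CA_C_O	120.5	degrees
a_N_CA_CB	110.4	degrees
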