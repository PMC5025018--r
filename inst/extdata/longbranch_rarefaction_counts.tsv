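#OTU ID	A	B
OTU.16340	52	1
OTU.17317	17	4
OTU.20	70	18
OTU.37867	59	10
OTU.37990	7	59
OTU.38187	646	115
OTU.38446	6	8
OTU.45429	218	6
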