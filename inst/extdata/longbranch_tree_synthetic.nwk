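((((OTU.16340:0.1,OTU.17317:0.1):0.1,(OTU.20:0.1,OTU.37867:0.1):0.1):0.2,(OTU.38187:0.1,OTU.45429:0.1):0.3):0.2,(OTU.37990:1.5,OTU.38446:0.2):0.3);
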