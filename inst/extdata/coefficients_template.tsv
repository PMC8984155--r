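gene	beta
CD38	NA
ALOX5	NA
TGFBR3	NA
ICAM3	NA
ANXA1	NA
ALCAM	NA
PECAM1	NA
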