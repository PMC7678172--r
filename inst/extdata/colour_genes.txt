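# Pigmentation genes represented among the Sanger-confirmed candidates
ATRN
DTNBP1
ELOVL3
FREM2
GGT1
GNPAT
L1CAM
LYST
MC1R
NOTCH1
NTRK1
PMEL
RECQL4
SEMA3C
SEMA4A
SHROOM2
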