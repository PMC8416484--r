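# Conventional side-chain and terminal pKa values, version 1.
# Columns: group<TAB>pKa<TAB>polarity. NTERM/CTERM rows set terminal pKas.
D	3.65	acidic
E	4.25	acidic
C	8.3	acidic
Y	10.07	acidic
H	6.0	basic
K	10.53	basic
R	12.48	basic
NTERM	8.0	basic
CTERM	3.1	acidic
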