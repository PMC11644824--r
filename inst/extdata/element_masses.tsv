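# Monoisotopic masses in Da (CODATA/NIST). "proton" and "electron" rows are
# particle constants used for adduct arithmetic, not element symbols.
symbol	monoisotopic_mass
C	12.0
H	1.00782503207
N	14.00307400
O	15.99491462
S	31.97207100
Na	22.98976928
P	30.97376163
proton	1.00727646
electron	0.00054858
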