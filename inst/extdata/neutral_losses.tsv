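# Neutral losses observed for triterpenoid skeletons; masses are computed
# from the formula column at load time (single source of truth).
label	formula
H2O	H2O
CO	CO
HCOOH	CH2O2
C5H8O2	C5H8O2
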