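# Query features from five plant-extract screens. RT, adduct hypothesis and
# fragment lists are reported values; precursor m/z values were not reported
# and are reconstructed from the reference-standard table (measured library
# m/z for protonated rows, calculated adduct m/z for sodiated rows).
# expected_compound maps adduct-level labels to the parent reference standard.
source	expected_compound	rt	precursor_mz	adduct	fragments
Peganum harmala	beta-Neriursate	10.53	575.4124	[M+H]+	220.9341
Camellia sinensis	Butyl ester of glycyrrhetinic acid	11.18	527.4097	[M+H]+	425.3459;288.9212;220.9335;189.1656;175.1472;149.0973
Aegle marmelos	beta-Neriursate	9.94	597.3914	[M+Na]+	509.2737;288.9202;259.1144;215.0896;171.0639;155.0685
Adhatoda vasica	Silymin A	9.95	507.3081	[M+Na]+	421.2227;390.2389;243.1232;155.0704
Papaver somniferum	Silymin A	9.97	507.3081	[M+Na]+	155.0693
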