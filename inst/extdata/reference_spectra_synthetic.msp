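Name: beta-Neriursate
Formula: C38H54O4
Adduct: [M+H]+
PrecursorMZ: 575.4095
RT: 10.35
CollisionEnergy: ramp 25-62.5
Mode: auto
Comment: synthetic library spectrum; reported fragment values plus in-silico neutral-loss ions
Num Peaks: 9
155.0685 1800
171.0639 1500
215.0896 2100
220.9341 2600
259.1144 1400
288.9202 2900
509.2737 1200
529.4040 4200
557.3989 5200

Name: Butyl ester of glycyrrhetinic acid
Formula: C34H54O4
Adduct: [M+H]+
PrecursorMZ: 527.4095
RT: 10.89
CollisionEnergy: ramp 25-62.5
Mode: auto
Comment: synthetic library spectrum; reported fragment values plus in-silico neutral-loss ions
Num Peaks: 8
149.0973 2300
175.1472 1900
189.1656 2500
220.9335 1600
288.9212 1400
425.3459 5100
481.4040 3600
509.3989 4400

Name: Silymin A
Formula: C30H44O5
Adduct: [M+Na]+
PrecursorMZ: 507.3081
RT: 9.9
CollisionEnergy: ramp 25-62.5
Mode: auto
Comment: synthetic library spectrum; reported fragment values
Num Peaks: 4
155.0704 2100
243.1232 1700
390.2389 2600
421.2227 3900

Name: Ilelatifol D
Formula: C30H46O4
Adduct: [M+H]+
PrecursorMZ: 471.3469
RT: 9.11
CollisionEnergy: 20
Mode: targeted
Comment: synthetic library spectrum; in-silico water and water+CO loss ions
Num Peaks: 2
425.3414 6200
453.3363 4800

Name: Glycyrrhetic acid
Formula: C30H46O4
Adduct: [M+H]+
PrecursorMZ: 471.3469
RT: 9.86
CollisionEnergy: 20
Mode: targeted
Comment: synthetic library spectrum; in-silico water loss and RDA diagnostic ion
Num Peaks: 2
249.1856 3500
453.3363 7200

Name: Lantanilic acid
Formula: C35H52O6
Adduct: [M+Na]+
PrecursorMZ: 591.3656
RT: 10.43
CollisionEnergy: ramp 25-62.5
Mode: auto
Comment: synthetic library spectrum; reported sodium-adduct fragment values
Num Peaks: 2
491.3195 4100
545.3714 3300
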