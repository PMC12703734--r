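# GB-Neck2 (igb = 8) per-element parameters, version 1.
# screen: HCT descreening scale applied to the reduced intrinsic radius.
# alpha/beta/gamma: coefficients of the tanh rescaling of the inverse
# effective radius. The 'default' row covers elements outside H/C/N/O/S.
element	screen	alpha	beta	gamma
H	1.425952	0.788440	0.798699	0.437334
C	1.058554	0.733756	0.506378	0.205844
N	0.733599	0.503364	0.316828	0.192915
O	1.061039	0.867814	0.876635	0.387882
S	-0.703469	0.867814	0.876635	0.387882
default	0.500000	1.000000	0.800000	4.850000
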