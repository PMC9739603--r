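name	smarts	class
HBD1	[#7!H0,#8!H0]	hydrogen-bond
HBD2	[#7!H0,#8!H0,#16!H0]	hydrogen-bond
HBA	[#7,#8;!+]	hydrogen-bond
HP1	[CX4]	hydrophobic
HP2	[CX3]=[CX3]	hydrophobic
HP3	[CX2]#[CX2]	hydrophobic
PIPI	a1aaaaa1	aromatic
PICat	[#7+]	ionic
SaltBridge	[#8-]	ionic
Hal	[Cl,Br,I]	halogen
F	F	halogen
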