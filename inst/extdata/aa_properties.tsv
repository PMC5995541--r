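aa	property
A	ALIPHATIC
V	ALIPHATIC
L	ALIPHATIC
I	ALIPHATIC
F	AROMATIC
W	AROMATIC
Y	AROMATIC
D	CHARGED
E	CHARGED
K	CHARGED
R	CHARGED
A	HYDROPHOBIC
V	HYDROPHOBIC
L	HYDROPHOBIC
I	HYDROPHOBIC
M	HYDROPHOBIC
F	HYDROPHOBIC
W	HYDROPHOBIC
C	HYDROPHOBIC
S	POLAR
T	POLAR
N	POLAR
Q	POLAR
Y	POLAR
H	POLAR
C	POLAR
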