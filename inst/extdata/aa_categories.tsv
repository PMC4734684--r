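aa	category
R	positive-charged
H	positive-charged
K	positive-charged
D	negative-charged
E	negative-charged
S	polar-uncharged
T	polar-uncharged
N	polar-uncharged
Q	polar-uncharged
A	hydrophobic
I	hydrophobic
L	hydrophobic
M	hydrophobic
F	hydrophobic
W	hydrophobic
Y	hydrophobic
V	hydrophobic
C	special
G	special
P	special
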