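residue	avg_mass
A	71.0780
C	103.1430
D	115.0875
E	129.1141
F	147.1739
G	57.0514
H	137.1394
I	113.1577
K	128.1724
L	113.1577
M	131.1961
N	114.1027
P	97.1153
Q	128.1293
R	156.1858
S	87.0774
T	101.1040
V	99.1311
W	186.2100
Y	163.1733
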