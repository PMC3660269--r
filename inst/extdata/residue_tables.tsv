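# Per-residue constants.
# mass: average residue mass in Da (Expasy-style; add one water, 18.01524 Da, per chain)
# kd: Kyte-Doolittle hydropathy
# abundance: Swiss-Prot-wide natural-abundance frequency (release-era stats; renormalized on load)
residue	mass	kd	abundance
A	71.0788	1.8	0.0826
R	156.1875	-4.5	0.0553
N	114.1038	-3.5	0.0406
D	115.0886	-3.5	0.0546
C	103.1388	2.5	0.0137
Q	128.1307	-3.5	0.0393
E	129.1155	-3.5	0.0675
G	57.0519	-0.4	0.0708
H	137.1411	-3.2	0.0227
I	113.1594	4.5	0.0596
L	113.1594	3.8	0.0966
K	128.1741	-3.9	0.0584
M	131.1926	1.9	0.0242
F	147.1766	2.8	0.0386
P	97.1167	-1.6	0.0470
S	87.0782	-0.8	0.0656
T	101.1051	-0.7	0.0534
W	186.2132	-0.9	0.0108
Y	163.1760	-1.3	0.0292
V	99.1326	4.2	0.0687
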